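# shared pipeline fixture: writes a complete synthetic input bundle + config
make_run_config <- function(dir, seed = 1, n_trees = 4,
                            cfg = synthetic_config(
                              n_terms = 50, n_genes = 250,
                              n_disease_genes = 20, disease_term_count = 3,
                              seed = 33)) {
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  write_obo(ont, file.path(dir, "ontology.obo"))
  write_annotations(syn$annotations, file.path(dir, "annotations.tsv"))
  write_disease_definitions(syn$disease, file.path(dir, "disease.tsv"))
  writeLines(syn$planted_genes, file.path(dir, "planted.txt"))
  config <- list(
    paths = list(ontology = file.path(dir, "ontology.obo"),
                 annotations = file.path(dir, "annotations.tsv"),
                 diseases = file.path(dir, "disease.tsv"),
                 output = file.path(dir, "out"),
                 gold_standards = list(list(label = "planted",
                                            positives = file.path(dir, "planted.txt")))),
    params = list(n_trees = n_trees, iterations = 100),
    seed = seed)
  list(config = config, syn = syn, ont = ont)
}

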