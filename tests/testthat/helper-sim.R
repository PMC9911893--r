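# Shared simulated fixtures, built once per test run.

.test_cache <- new.env(parent = emptyenv())

# small two-WGD genome for module-level tests
small_sim <- function() {
  if (is.null(.test_cache$small))
    .test_cache$small <- simulate_genome(simulation_params(
      n_chromosomes = 2, genes_per_chromosome = 80, n_tf_families = 2,
      tf_family_size = 8, codon_length = c(60, 90), seed = 101))
  .test_cache$small
}

# one full default-condition pipeline run shared by the end-to-end tests
full_run <- function() {
  if (is.null(.test_cache$full)) {
    out <- file.path(tempdir(), "wgdretain-full-run")
    .test_cache$full <- run_pipeline(
      pipeline_config(simulate = list(), seed = 2024), outdir = out)
    .test_cache$full_outdir <- out
  }
  .test_cache$full
}

full_run_outdir <- function() {
  full_run()
  .test_cache$full_outdir
}

# majority ground-truth WGD label of an accepted event
event_truth_labels <- function(run) {
  acc <- run$events[run$events$status == "accepted", , drop = FALSE]
  ds <- run$dataset
  sof <- stats::setNames(ds$genes$species, ds$genes$gene_id)
  vapply(seq_len(nrow(acc)), function(i) {
    ga <- acc$child_a_genes[[i]]; gb <- acc$child_b_genes[[i]]
    ga <- ga[sof[ga] == "MC"]; gb <- gb[sof[gb] == "MC"]
    prs <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    labs <- true_pair_label(ds$true_pair_labels, prs$a, prs$b)
    names(sort(table(labs), decreasing = TRUE))[1]
  }, character(1))
}
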