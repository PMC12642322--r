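# Shared fixtures. Expensive pipeline runs are memoised across test files so
# several acceptance checks can share one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# tiny synthetic study for fast unit tests
tiny_config <- function(seed = 42L, ...) {
  synth_config(islets_per_donor = 24L, islets_per_donor_nd = 12L,
               n_features = 240L, immune_module_size = 40L,
               bcell_module_size = 30L, n_background_modules = 5L,
               blocks_per_donor = 2L, n_reference_pools = 4L,
               seed = seed, ...)
}

tiny_dataset <- function(seed = 42L, ...) {
  key <- paste0("tiny_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, generate_dataset(tiny_config(seed = seed, ...)))
}

# reduced-islet study: all structural defaults, fewer islet sections per
# donor so the nested-CV selection stays tractable in a test run
desk_config <- function(seed) {
  synth_config(islets_per_donor = 30L, islets_per_donor_nd = 15L, seed = seed)
}

desk_pipeline <- function(seed) {
  cached(paste0("pipeline_", seed), {
    cfg <- pipeline_config(seed = seed, synth = desk_config(seed))
    run_pipeline(cfg)
  })
}

# simple per-donor preprocessing chain used by several tests
preprocess_dataset <- function(ds, min_completeness = 0.5) {
  meta_i <- ds$metadata[ds$metadata$is_reference == 0L, , drop = FALSE]
  per <- list()
  for (d in unique(meta_i$donor_id)) {
    ids <- meta_i$sample_id[meta_i$donor_id == d]
    md <- ds$abundance[, ids, drop = FALSE]
    attr(md, "scale_tag") <- "log2"
    md <- combat_correct(median_polish_normalize(log2_and_center(md)),
                         meta_i$block[match(ids, meta_i$sample_id)])
    per[[d]] <- md
  }
  asm <- completeness_filter(assemble_cross_donor(per), meta_i, min_completeness)
  list(abundance = asm, meta = meta_i)
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
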