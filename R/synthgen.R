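#' Configuration for the synthetic single-islet study
#'
#' Defines the simulated study: three presymptomatic (stage 1) donors with
#' ~100 islet sections each and three non-diabetic (ND) controls with ~50
#' each, a module-structured proteome in which one planted module carries a
#' latent immune-activation gradient (pseudo-time, present only in stage-1
#' donors), one carries a beta-cell state latent that is depressed in a
#' subset of islets, tissue-block batch shifts, intensity-dependent (MNAR)
#' plus completely-random (MCAR) missingness, and replicate reference pools.
#'
#' @param n_donors_stage1,n_donors_nd donor counts per group.
#' @param islets_per_donor islet sections per stage-1 donor.
#' @param islets_per_donor_nd islet sections per ND donor.
#' @param blocks_per_donor tissue blocks (batches) within each donor.
#' @param n_features protein groups simulated.
#' @param immune_module_size,bcell_module_size planted module sizes; INS and
#'   ENTPD3 are named members of the beta-cell module, GCG a named
#'   non-member.
#' @param n_background_modules co-regulated background modules; features not
#'   in a module and not unstructured are split evenly among them.
#' @param unstructured_fraction fraction of features outside any module
#'   (pure measurement noise around their baseline), as in real proteomes
#'   where much of the proteome is not co-regulated.
#' @param immune_effect log2 units of immune-feature shift per unit
#'   pseudo-time.
#' @param bcell_effect log2 units of beta-cell-feature shift per unit
#'   beta-cell latent.
#' @param bcell_loss_fraction,bcell_loss_fraction_nd fraction of islets per
#'   stage-1 / ND donor whose beta-cell latent is depressed (v ~ U(0, 0.3)
#'   instead of U(0.5, 1)).
#' @param batch_sd SD (log2) of per-feature tissue-block offsets.
#' @param noise_sd SD (log2) of measurement noise; must be positive.
#' @param mnar_midpoint,mnar_slope logistic censoring of low intensities:
#'   an observation at log2 intensity x is dropped with probability
#'   `plogis(mnar_slope * (mnar_midpoint - x))`.
#' @param mcar_rate additional completely-at-random missingness.
#' @param n_reference_pools replicate reference-pool samples (noisy copies of
#'   the grand mean profile) spread across donors.
#' @param ref_noise_sd SD (log2) of reference-pool replicate noise.
#' @param cd3_intercept,cd3_slope logistic link of the binary CD3 call to the
#'   pseudo-time u: P(CD3+) = plogis(cd3_intercept + cd3_slope * u).
#' @param nd_jitter optional small uniform jitter on the ND pseudo-time
#'   (default 0: u is exactly 0 in ND donors).
#' @param seed integer seed; required, there is no implicit entropy.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_donors_stage1 = 3L, n_donors_nd = 3L,
                         islets_per_donor = 100L, islets_per_donor_nd = 50L,
                         blocks_per_donor = 3L,
                         n_features = 1000L,
                         immune_module_size = 100L, bcell_module_size = 80L,
                         n_background_modules = 18L,
                         unstructured_fraction = 0.3,
                         immune_effect = 2, bcell_effect = 2,
                         bcell_loss_fraction = 0.25, bcell_loss_fraction_nd = 0.08,
                         batch_sd = 0.5, noise_sd = 0.5,
                         mnar_midpoint = 18, mnar_slope = 1, mcar_rate = 0.02,
                         n_reference_pools = 6L, ref_noise_sd = 0.1,
                         cd3_intercept = -2, cd3_slope = 4,
                         nd_jitter = 0,
                         seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(seed)) stop("synth_config: a seed is required (no implicit entropy)")
  counts <- c("n_donors_stage1", "n_donors_nd", "islets_per_donor",
              "islets_per_donor_nd", "blocks_per_donor", "n_features",
              "immune_module_size", "bcell_module_size", "n_background_modules")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("synth_config: '", f, "' must be a positive integer count")
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(cfg$n_reference_pools) || cfg$n_reference_pools < 0)
    stop("synth_config: n_reference_pools must be a non-negative count")
  cfg$n_reference_pools <- as.integer(cfg$n_reference_pools)
  if (cfg$immune_module_size + cfg$bcell_module_size > cfg$n_features)
    stop("synth_config: immune_module_size + bcell_module_size exceeds n_features")
  for (f in c("bcell_loss_fraction", "bcell_loss_fraction_nd", "mcar_rate",
              "unstructured_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop("synth_config: '", f, "' must be in [0,1]")
  }
  if (cfg$noise_sd <= 0) stop("synth_config: noise_sd must be positive")
  if (cfg$batch_sd < 0 || cfg$immune_effect < 0 || cfg$bcell_effect < 0)
    stop("synth_config: scales must be non-negative")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

# Named marker symbols planted into the two signature-bearing modules.
.immune_names <- c("STAT1", "WARS1", "HLA-A", "HLA-B", "CD74", "TAP1",
                   "ISG15", "MX1", "GBP1", "PSMB8")
.bcell_names <- c("INS", "ENTPD3", "IAPP", "PCSK1", "ERO1B", "HADH",
                  "UCHL1", "NPTX2")

.feature_layout <- function(cfg) {
  n_imm <- cfg$immune_module_size
  n_bc <- cfg$bcell_module_size
  n_rest <- cfg$n_features - n_imm - n_bc
  n_grey <- min(n_rest, round(cfg$unstructured_fraction * cfg$n_features))
  n_bg <- n_rest - n_grey
  imm <- c(.immune_names[seq_len(min(n_imm, length(.immune_names)))],
           sprintf("IMM%04d", seq_len(max(0L, n_imm - length(.immune_names)))))
  bc <- c(.bcell_names[seq_len(min(n_bc, length(.bcell_names)))],
          sprintf("BCL%04d", seq_len(max(0L, n_bc - length(.bcell_names)))))
  module <- sort(rep(paste0("BG", sprintf("%02d", seq_len(cfg$n_background_modules))),
                     length.out = n_bg))
  bg <- sprintf("BG%04d", seq_len(n_bg))
  # GCG rides the first background (alpha-cell-like) module, not the
  # beta-cell module, so anchor-correlation ranking can be checked against a
  # named non-member.
  if (n_bg > 0L) bg[1L] <- "GCG"
  grey <- sprintf("UNS%04d", seq_len(n_grey))
  list(feature = c(imm, bc, bg, grey),
       module = c(rep("immune", n_imm), rep("bcell", n_bc), module,
                  rep("none", n_grey)))
}

#' Generate a synthetic single-islet proteomics dataset
#'
#' Deterministic for a fixed seed; one RNG stream per dataset, split
#' hierarchically per donor so regenerating a donor does not disturb the
#' others. Stage-1 islets draw their immune latent u ~ U(0,1); ND islets have
#' u = 0 (plus optional jitter). The beta-cell latent v is drawn
#' independently of u, with a depressed subset per donor. Block offsets are
#' mean-zero per feature within each donor. Missingness combines logistic
#' low-intensity censoring with a constant MCAR rate. Reference pools are
#' noisy replicates of the grand mean profile.
#'
#' @param config a [synth_config()].
#' @return list of class `synthetic_dataset` with elements `abundance`
#'   (log2 matrix with missing entries), `metadata` (see [read_metadata()])
#'   and `truth` (pseudo-time, beta-cell latent, planted memberships,
#'   loadings, batch offsets).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    lay <- .feature_layout(cfg)
    p <- cfg$n_features
    # baseline log2 intensities span the usual label-free dynamic range;
    # loadings give within-module correlations around 0.85-0.95, the
    # tightness of reported fine-grained co-expression clusters
    mu <- stats::rnorm(p, mean = 22, sd = 4.5)
    lambda <- stats::runif(p, 1.5, 2.5)
    names(mu) <- names(lambda) <- lay$feature
    # INS and ENTPD3 get the strongest beta-cell loadings so the low-insulin
    # rule (4-fold below the donor median) has the dynamic range it needs;
    # the named hormone markers sit at the top of the intensity range (as in
    # real islet proteomes), keeping them clear of the censoring tail
    lambda["INS"] <- 2.5
    lambda["ENTPD3"] <- 2.2
    mu["INS"] <- 28
    mu["ENTPD3"] <- 24
    if ("GCG" %in% names(mu)) mu["GCG"] <- 27

    n_donors <- cfg$n_donors_stage1 + cfg$n_donors_nd
    donor_ids <- c(sprintf("S1_%02d", seq_len(cfg$n_donors_stage1)),
                   sprintf("ND_%02d", seq_len(cfg$n_donors_nd)))
    donor_grp <- rep(c("stage1", "nd"), c(cfg$n_donors_stage1, cfg$n_donors_nd))
    donor_seeds <- sample.int(.Machine$integer.max - 1L, n_donors)
    ref_seed <- sample.int(.Machine$integer.max - 1L, 1L)

    cols <- list(); meta <- list(); u_all <- list(); v_all <- list()
    offsets <- list()
    bg_mods <- setdiff(unique(lay$module), c("immune", "bcell", "none"))
    imm_idx <- lay$module == "immune"
    bc_idx <- lay$module == "bcell"

    for (d in seq_len(n_donors)) {
      set.seed(donor_seeds[d])
      stage1 <- donor_grp[d] == "stage1"
      n <- if (stage1) cfg$islets_per_donor else cfg$islets_per_donor_nd
      u <- if (stage1) stats::runif(n) else stats::runif(n, 0, cfg$nd_jitter)
      if (!stage1 && cfg$nd_jitter == 0) u <- rep(0, n)
      loss_frac <- if (stage1) cfg$bcell_loss_fraction else cfg$bcell_loss_fraction_nd
      lost <- stats::runif(n) < loss_frac
      v <- ifelse(lost, stats::runif(n, 0, 0.3), stats::runif(n, 0.5, 1))
      cd3 <- stats::rbinom(n, 1L, stats::plogis(cfg$cd3_intercept + cfg$cd3_slope * u))
      block <- rep(seq_len(cfg$blocks_per_donor), length.out = n)
      block_lab <- paste0(donor_ids[d], "_B", block)

      # module factors: immune column is u, bcell is v, backgrounds N(0,1)
      fac <- matrix(stats::rnorm(length(bg_mods) * n), nrow = length(bg_mods),
                    dimnames = list(bg_mods, NULL))
      sig <- matrix(mu, nrow = p, ncol = n, dimnames = list(lay$feature, NULL))
      sig[imm_idx, ] <- sig[imm_idx, ] +
        cfg$immune_effect * tcrossprod(lambda[imm_idx], u)
      sig[bc_idx, ] <- sig[bc_idx, ] +
        cfg$bcell_effect * tcrossprod(lambda[bc_idx], v)
      for (bm in bg_mods) {
        rows <- lay$module == bm
        sig[rows, ] <- sig[rows, ] + tcrossprod(lambda[rows], fac[bm, ])
      }

      # mean-zero tissue-block offsets per feature within the donor
      off <- matrix(stats::rnorm(p * cfg$blocks_per_donor, 0, cfg$batch_sd),
                    nrow = p,
                    dimnames = list(lay$feature,
                                    paste0(donor_ids[d], "_B",
                                           seq_len(cfg$blocks_per_donor))))
      off <- off - rowMeans(off)
      sig <- sig + off[, block, drop = FALSE]
      sig <- sig + matrix(stats::rnorm(p * n, 0, cfg$noise_sd), nrow = p)

      ids <- sprintf("%s_i%03d", donor_ids[d], seq_len(n))
      colnames(sig) <- ids
      cols[[d]] <- sig
      offsets[[donor_ids[d]]] <- off
      u_all[[d]] <- stats::setNames(u, ids)
      v_all[[d]] <- stats::setNames(v, ids)
      meta[[d]] <- data.frame(sample_id = ids, donor_id = donor_ids[d],
                              group = donor_grp[d], block = block_lab,
                              cd3 = cd3, is_reference = 0L,
                              stringsAsFactors = FALSE)
    }

    abundance <- do.call(cbind, cols)
    metadata <- do.call(rbind, meta)

    if (cfg$n_reference_pools > 0L) {
      set.seed(ref_seed)
      grand <- rowMeans(abundance)
      refs <- matrix(grand, nrow = p, ncol = cfg$n_reference_pools) +
        matrix(stats::rnorm(p * cfg$n_reference_pools, 0, cfg$ref_noise_sd), nrow = p)
      rid <- sprintf("REF_%02d", seq_len(cfg$n_reference_pools))
      colnames(refs) <- rid
      rownames(refs) <- rownames(abundance)
      host <- rep(seq_len(n_donors), length.out = cfg$n_reference_pools)
      rmeta <- data.frame(sample_id = rid, donor_id = donor_ids[host],
                          group = donor_grp[host],
                          block = paste0(donor_ids[host], "_B1"),
                          cd3 = NA_integer_, is_reference = 1L,
                          stringsAsFactors = FALSE)
      abundance <- cbind(abundance, refs)
      metadata <- rbind(metadata, rmeta)
    }

    # intensity-dependent + completely-random missingness
    p_mnar <- stats::plogis(cfg$mnar_slope * (cfg$mnar_midpoint - abundance))
    if (cfg$mnar_slope == 0) p_mnar[] <- 0
    p_miss <- 1 - (1 - p_mnar) * (1 - cfg$mcar_rate)
    drop <- matrix(stats::runif(length(abundance)) < p_miss, nrow = p)
    abundance[drop] <- NA_real_
    attr(abundance, "scale_tag") <- "log2"
    .check_abundance(abundance)

    truth <- list(
      pseudo_time = unlist(u_all),
      bcell_latent = unlist(v_all),
      planted_immune_members = lay$feature[imm_idx],
      planted_bcell_members = lay$feature[bc_idx],
      module = stats::setNames(lay$module, lay$feature),
      loadings = lambda,
      batch_offsets = offsets,
      config = cfg
    )
    structure(list(abundance = abundance, metadata = metadata, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset as plain TSV files
#'
#' Emits `abundance.tsv` (features x samples, empty cell = missing),
#' `metadata.tsv`, and two truth tables (`truth_samples.tsv`,
#' `truth_features.tsv`). Round-trips losslessly through [read_abundance()]
#' and [read_metadata()].
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (nrow(ds$abundance) == 0L) stop("refusing to write a dataset with no features")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  paths <- file.path(dir, c("abundance.tsv", "metadata.tsv",
                            "truth_samples.tsv", "truth_features.tsv"))
  write_abundance(ds$abundance, paths[1L])
  write_metadata(ds$metadata, paths[2L])
  samp <- data.frame(sample_id = names(ds$truth$pseudo_time),
                     pseudo_time = ds$truth$pseudo_time,
                     bcell_latent = ds$truth$bcell_latent[names(ds$truth$pseudo_time)],
                     stringsAsFactors = FALSE)
  utils::write.table(samp, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  feat <- data.frame(feature = names(ds$truth$module),
                     module = ds$truth$module,
                     loading = ds$truth$loadings[names(ds$truth$module)],
                     stringsAsFactors = FALSE)
  utils::write.table(feat, paths[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Build a toy gene-set collection around a planted feature set
#'
#' One set equals the planted members (named `PLANTED_IMMUNE_RESPONSE`);
#' the remaining sets are drawn uniformly from the non-planted universe.
#' Useful as a stand-in for GO:BP exports when exercising ORA and CAMERA-PR
#' on synthetic data.
#'
#' @param n_sets total number of sets, the planted one included (0 gives an
#'   empty collection).
#' @param set_size size of the random sets.
#' @param planted character vector of planted features (deduplicated with a
#'   warning if needed).
#' @param universe full feature universe; must contain all planted features.
#' @param seed integer seed for the random sets.
#' @return gene-set collection as for [read_gmt()].
#' @export
make_toy_goldset <- function(n_sets, set_size, planted, universe, seed = 1L) {
  if (n_sets == 0L) {
    return(structure(list(), description = character(0), provenance = "toy goldset"))
  }
  if (anyDuplicated(planted)) {
    warning("duplicate planted features deduplicated")
    planted <- unique(planted)
  }
  missing <- setdiff(planted, universe)
  if (length(missing))
    stop("planted features not in universe: ", paste(utils::head(missing, 5L), collapse = ", "))
  if (set_size > length(universe)) stop("set_size exceeds universe size")
  bg <- setdiff(universe, planted)
  .with_seed(seed, {
    sets <- list(PLANTED_IMMUNE_RESPONSE = planted)
    if (n_sets > 1L) {
      rnd <- lapply(seq_len(n_sets - 1L), function(i)
        sample(bg, min(set_size, length(bg))))
      names(rnd) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets - 1L))
      sets <- c(sets, rnd)
    }
    structure(sets,
              description = stats::setNames(rep("synthetic", length(sets)), names(sets)),
              provenance = "toy goldset")
  })
}
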