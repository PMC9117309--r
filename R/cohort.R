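#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of two groups ("A", modelling the clinical group with a
#' planted reduction of within-module connectivity, and "B", the comparison
#' group) of subjects whose functional connectivity matrices follow a modular
#' block structure.  Defaults mirror the design the pipeline is meant for:
#' 200 ROIs in 7 modules, within-module correlation 0.30 against a 0.10
#' background (typical within- versus between-network Pearson FC
#' magnitudes), a 0.15 within-module reduction in group A, and subject-level
#' jitter with standard deviation 0.05.  With these values group B's
#' within/between weight gap is four noise standard deviations (strong
#' module segregation) while group A's is one (weak segregation), so the
#' planted effect survives binarization.
#'
#' @param n_rois number of ROIs (graph nodes).
#' @param n_subjects_per_group subjects per group.
#' @param n_blocks number of modules in the planted block structure; must not
#'   exceed `n_rois`.
#' @param within_block_mu mean correlation inside blocks for group B, in
#'   (-1, 1), non-zero.
#' @param between_block_mu mean correlation across blocks, in (-1, 1),
#'   non-zero.
#' @param group_effect additive reduction of `within_block_mu` applied to
#'   group A; must be >= 0.
#' @param effect_blocks optional integer vector of block labels the group
#'   effect is confined to; `NULL` (default) applies it to every block.
#' @param noise_sd standard deviation of the symmetric subject-level jitter
#'   added to off-diagonal entries.
#' @param n_timepoints optional; when set, each subject is realized as a
#'   multivariate Gaussian ROI time series of this length and the FC matrix
#'   is its sample Pearson correlation.
#' @param score_slope,score_noise_sd linear link and noise for synthetic
#'   clinical scores (see [generate_clinical_scores()]).
#' @param seed integer master seed; per-subject substreams are derived from
#'   it by fixed offsets.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 200, n_subjects_per_group = 50,
                        n_blocks = 7, within_block_mu = 0.30,
                        between_block_mu = 0.10, group_effect = 0.15,
                        effect_blocks = NULL, noise_sd = 0.05,
                        n_timepoints = NULL, score_slope = 1,
                        score_noise_sd = 0.1, seed = 1) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop_input("invalid cohort_spec field '%s': must be a positive integer, got %s",
                 nm, paste(x, collapse = ","))
  }
  chk_count(n_rois, "n_rois")
  chk_count(n_subjects_per_group, "n_subjects_per_group")
  chk_count(n_blocks, "n_blocks")
  if (!is.null(n_timepoints)) chk_count(n_timepoints, "n_timepoints")
  if (n_blocks > n_rois)
    stop_input("invalid cohort_spec field 'n_blocks': %d blocks cannot be non-empty with %d ROIs",
               n_blocks, n_rois)
  for (nm in c("within_block_mu", "between_block_mu")) {
    v <- get(nm)
    if (!is.finite(v) || v == 0 || abs(v) >= 1)
      stop_input("invalid cohort_spec field '%s': need 0 < |value| < 1, got %s",
                 nm, v)
  }
  if (!is.finite(group_effect) || group_effect < 0)
    stop_input("invalid cohort_spec field 'group_effect': must be >= 0, got %s",
               group_effect)
  if (!is.null(effect_blocks)) {
    effect_blocks <- as.integer(effect_blocks)
    if (anyNA(effect_blocks) || any(effect_blocks < 1 | effect_blocks > n_blocks))
      stop_input("invalid cohort_spec field 'effect_blocks': labels must be in 1..%d",
                 n_blocks)
  }
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_input("invalid cohort_spec field 'noise_sd': must be >= 0, got %s",
               noise_sd)
  if (!is.finite(score_noise_sd) || score_noise_sd < 0)
    stop_input("invalid cohort_spec field 'score_noise_sd': must be >= 0")
  if (length(seed) != 1 || is.na(seed))
    stop_input("invalid cohort_spec field 'seed'")
  structure(list(n_rois = as.integer(n_rois),
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_blocks = as.integer(n_blocks),
                 within_block_mu = within_block_mu,
                 between_block_mu = between_block_mu,
                 group_effect = group_effect, effect_blocks = effect_blocks,
                 noise_sd = noise_sd,
                 n_timepoints = if (is.null(n_timepoints)) NULL
                                else as.integer(n_timepoints),
                 score_slope = score_slope, score_noise_sd = score_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Block assignment of ROIs to planted modules
#'
#' ROIs `1..n_rois` are split into `n_blocks` contiguous, near-equal,
#' non-empty blocks.
#'
#' @param spec a [cohort_spec()].
#' @return Integer vector of block labels, length `n_rois`.
#' @export
block_assignment <- function(spec) {
  sizes <- rep(spec$n_rois %/% spec$n_blocks, spec$n_blocks)
  extra <- spec$n_rois %% spec$n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(spec$n_blocks), times = sizes)
}

# Nearest valid correlation matrix: clip eigenvalues at a small positive
# floor, reconstruct, renormalize to unit diagonal.  A matrix that is already
# positive definite (all eigenvalues >= floor) is returned untouched so that
# noiseless block constructions keep their exact entries.
project_correlation <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  m2 <- (m2 + t(m2)) / 2
  m2[m2 > 1] <- 1; m2[m2 < -1] <- -1
  diag(m2) <- 1
  m2
}

block_target <- function(spec, group) {
  blocks <- block_assignment(spec)
  same <- outer(blocks, blocks, "==")
  m <- ifelse(same, spec$within_block_mu, spec$between_block_mu)
  if (group == "A" && spec$group_effect > 0) {
    hit <- if (is.null(spec$effect_blocks)) rep(TRUE, length(blocks))
           else blocks %in% spec$effect_blocks
    aff <- same & outer(hit, hit, "&")
    m[aff] <- m[aff] - spec$group_effect
  }
  diag(m) <- 1
  m
}

#' Generate a synthetic two-group cohort of FC matrices
#'
#' Each subject's matrix is a block-constant correlation target (group A with
#' `within_block_mu - group_effect` inside blocks, group B with
#' `within_block_mu`; `between_block_mu` elsewhere) plus symmetric Gaussian
#' jitter of standard deviation `noise_sd`, projected to the nearest valid
#' correlation matrix.  When `n_timepoints` is set the subject is instead
#' realized as a multivariate Gaussian time series with that covariance and
#' the emitted FC matrix is the sample Pearson correlation of the series
#' (stored in attribute `"timeseries"` of each matrix).  Generation is a pure
#' function of `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `fc` (list of [fc_matrix()], group A first),
#'   `subjects` (data.frame with columns `subject_id`, `group`, `age`,
#'   `gender`, `clinical_score`) and `blocks` (the [block_assignment()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_rois
  npg <- spec$n_subjects_per_group
  targets <- list(A = block_target(spec, "A"), B = block_target(spec, "B"))
  fc <- vector("list", 2 * npg)
  ids <- character(2 * npg)
  groups <- character(2 * npg)
  off <- which(upper.tri(matrix(0, n, n)))
  k <- 0
  for (grp in c("A", "B")) {
    for (s in seq_len(npg)) {
      k <- k + 1
      ids[k] <- sprintf("%s%03d", grp, s)
      groups[k] <- grp
      m <- targets[[grp]]
      fc[[k]] <- with_seed(substream_seed(spec$seed, k), {
        if (spec$noise_sd > 0) {
          jit <- numeric(length(off))
          jit <- rnorm(length(off), sd = spec$noise_sd)
          j <- matrix(0, n, n)
          j[upper.tri(j)] <- jit
          m <- m + j + t(j)
          m[m > 0.99] <- 0.99; m[m < -0.99] <- -0.99
          diag(m) <- 1
          m <- project_correlation(m)
        }
        if (!is.null(spec$n_timepoints)) {
          m <- project_correlation(m)  # ensure PD for the Cholesky draw
          ch <- chol(m + diag(1e-10, n))
          z <- matrix(rnorm(spec$n_timepoints * n), spec$n_timepoints, n)
          ts <- t(z %*% ch)  # ROIs x timepoints
          out <- pearson_fc(roi_timeseries(ts, subject_id = ids[k]))
          attr(out, "timeseries") <- ts
          out
        } else {
          fc_matrix(m, subject_id = ids[k])
        }
      })
    }
  }
  subjects <- with_seed(substream_seed(spec$seed, 999983), data.frame(
    subject_id = ids, group = groups,
    age = round(runif(2 * npg, 7, 58), 1),
    gender = ifelse(rbinom(2 * npg, 1, 0.15) == 1, "F", "M"),
    clinical_score = NA_real_, stringsAsFactors = FALSE))
  list(fc = fc, subjects = subjects, blocks = block_assignment(spec))
}

#' Attach synthetic clinical scores to group A subjects
#'
#' Emulates symptom-severity scores available only for the clinical group:
#' `score = score_slope * nodal_value + N(0, score_noise_sd)`, computed for
#' group A subjects only; group B keeps `NA` (scores unavailable, as for
#' typically developing subjects).
#'
#' @param subjects the subject data.frame from [generate_cohort()].
#' @param nodal_values numeric vector aligned with the group A rows of
#'   `subjects` (e.g. one node's AUC per subject).
#' @param spec the [cohort_spec()] (uses `score_slope`, `score_noise_sd`,
#'   `seed`).
#' @return `subjects` with `clinical_score` filled in for group A.
#' @export
generate_clinical_scores <- function(subjects, nodal_values, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ia <- which(subjects$group == "A")
  if (length(nodal_values) != length(ia))
    stop_input("nodal_values length %d != number of group A subjects %d",
               length(nodal_values), length(ia))
  noise <- with_seed(substream_seed(spec$seed, 424243),
                     rnorm(length(ia), sd = spec$score_noise_sd))
  subjects$clinical_score[ia] <- spec$score_slope * nodal_values + noise
  subjects
}

#' Generate a ROI-to-term table with planted enrichment
#'
#' Every ROI carries all `background_terms`; ROIs belonging to
#' `enriched_rsn` additionally carry each of `enriched_terms` independently
#' with probability `p_hit`.  A synthetic stand-in for meta-analytic
#' term-association data.
#'
#' @param atlas an [atlas_table()].
#' @param enriched_rsn RSN label present in the atlas.
#' @param enriched_terms,background_terms character vectors of terms.
#' @param p_hit per-ROI, per-term inclusion probability for enriched terms.
#' @param seed integer seed.
#' @return A data.frame with columns `roi_id`, `term` (the term table).
#' @export
generate_term_table <- function(atlas, enriched_rsn, enriched_terms,
                                background_terms, p_hit = 0.8, seed = 1) {
  validate_atlas(atlas)
  if (!enriched_rsn %in% atlas$rsn)
    stop_input("unknown RSN label '%s'; atlas has: %s", enriched_rsn,
               paste(unique(atlas$rsn), collapse = ", "))
  if (p_hit < 0 || p_hit > 1)
    stop_input("p_hit must be in [0, 1], got %s", p_hit)
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(atlas)), function(i) {
      terms <- background_terms
      if (atlas$rsn[i] == enriched_rsn && length(enriched_terms)) {
        hit <- runif(length(enriched_terms)) < p_hit
        terms <- c(terms, enriched_terms[hit])
      }
      if (!length(terms)) return(NULL)
      data.frame(roi_id = atlas$roi_id[i], term = terms,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write cohort artifacts as plain-text files
#'
#' FC matrices go to `<dir>/fc/<subject_id>.csv`, the subject table to
#' `<dir>/subjects.tsv` and the term table (if given) to `<dir>/terms.tsv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param term_table optional term table from [generate_term_table()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, term_table = NULL) {
  dir.create(file.path(dir, "fc"), recursive = TRUE, showWarnings = FALSE)
  for (fc in cohort$fc)
    write_fc_matrix(fc, file.path(dir, "fc", paste0(fc$subject_id, ".csv")))
  write.table(cohort$subjects, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(term_table))
    write.table(term_table, file.path(dir, "terms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
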