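#' Term frequency counts over an ROI set
#'
#' For each term, the number of ROIs in `rois` whose term list contains it
#' (ROI-level presence counting: a term listed twice for one ROI still
#' counts once for that ROI).
#'
#' @param rois integer ROI ids.
#' @param term_table data.frame with columns `roi_id`, `term` (see
#'   [generate_term_table()]).
#' @param terms optional term universe; defaults to all terms appearing for
#'   `rois`.
#' @return Named integer vector of counts.
#' @export
term_counts <- function(rois, term_table, terms = NULL) {
  rois <- unique(as.integer(rois))
  unknown <- setdiff(rois, unique(term_table$roi_id))
  if (length(unknown))
    stop_input("ROI id(s) not in term table: %s",
               paste(unknown, collapse = ", "))
  sub <- unique(term_table[term_table$roi_id %in% rois,
                           c("roi_id", "term")])
  if (is.null(terms)) terms <- sort(unique(sub$term))
  out <- stats::setNames(integer(length(terms)), terms)
  if (nrow(sub)) {
    tab <- table(factor(sub$term, levels = terms))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Surrogate-null term enrichment for significant ROI sets
#'
#' For each resting-state network's set of significant ROIs, compares the
#' observed term frequency counts with those of `n_surrogates` equal-size
#' ROI sets drawn uniformly at random (without replacement) from the chosen
#' pool.  The z-score `(observed - surrogate mean) / surrogate sd` is
#' converted to a one-sided upper-tail normal p-value, then
#' Benjamini-Hochberg adjusted across terms within each RSN.  A degenerate
#' null (zero surrogate sd) gets `p = 1/(n_surrogates + 1)` if the observed
#' count exceeds the surrogate mean and `p = 1` otherwise; the z-score is
#' reported as `Inf`/`0` accordingly.
#'
#' @param sig_rois_by_rsn named list: RSN label -> integer vector of
#'   significant ROI ids (each non-empty).
#' @param term_table data.frame with columns `roi_id`, `term`.
#' @param atlas an [atlas_table()]; defines the surrogate sampling pool.
#' @param n_surrogates number of surrogate draws (default 1000; >= 2).
#' @param seed integer seed (draws are deterministic under it).
#' @param pool `"atlas"` (default: all atlas ROIs) or `"rsn"` (restrict the
#'   surrogate pool to the RSN's own ROIs).
#' @param alpha FDR level for the significance flags.
#' @return data.frame with columns `rsn`, `term`, `observed`,
#'   `surrogate_mean`, `surrogate_sd`, `z`, `p`, `p_adjusted`, `significant`.
#' @export
surrogate_enrichment <- function(sig_rois_by_rsn, term_table, atlas,
                                 n_surrogates = 1000, seed = 1,
                                 pool = c("atlas", "rsn"), alpha = 0.05) {
  pool <- match.arg(pool)
  validate_atlas(atlas)
  if (n_surrogates < 2) stop_input("n_surrogates must be >= 2")
  if (is.null(names(sig_rois_by_rsn)) || any(!nzchar(names(sig_rois_by_rsn))))
    stop_input("sig_rois_by_rsn must be a named list (RSN labels)")
  res <- list()
  for (rsn in names(sig_rois_by_rsn)) {
    rois <- unique(as.integer(sig_rois_by_rsn[[rsn]]))
    if (!length(rois)) stop_input("empty significant set for RSN '%s'", rsn)
    obs <- term_counts(rois, term_table)
    if (!length(obs)) next
    pool_ids <- if (pool == "atlas") atlas$roi_id
                else atlas$roi_id[atlas$rsn == rsn]
    if (length(pool_ids) < length(rois))
      stop_input("surrogate pool smaller than the significant set for '%s'",
                 rsn)
    terms <- names(obs)
    surr <- with_seed(substream_seed(seed, match(rsn, names(sig_rois_by_rsn))), {
      vapply(seq_len(n_surrogates), function(s) {
        draw <- sample(pool_ids, length(rois), replace = FALSE)
        term_counts(draw, term_table, terms = terms)
      }, numeric(length(terms)))
    })
    surr <- matrix(surr, nrow = length(terms))
    mu <- rowMeans(surr)
    sdv <- apply(surr, 1, sd)
    z <- ifelse(sdv > 0, (obs - mu) / sdv,
                ifelse(obs > mu, Inf, 0))
    p <- ifelse(sdv > 0, pnorm(z, lower.tail = FALSE),
                ifelse(obs > mu, 1 / (n_surrogates + 1), 1))
    fdr <- bh_fdr(p, alpha)
    res[[rsn]] <- data.frame(rsn = rsn, term = terms, observed = as.integer(obs),
                             surrogate_mean = mu, surrogate_sd = sdv, z = z,
                             p = p, p_adjusted = fdr$p_adjusted,
                             significant = fdr$significant,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
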