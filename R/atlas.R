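#' Resting-state network labels
#'
#' The seven canonical resting-state networks (RSNs) of the 7-network
#' Schaefer parcellation, in their conventional order.
#'
#' @export
RSN_LABELS <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn",
                "Limbic", "Cont", "Default")

#' Construct and validate an atlas table
#'
#' An atlas assigns every ROI a unique, contiguous integer id, a name, one of
#' seven resting-state-network labels and an MNI centroid in millimetres.
#'
#' @param roi_id integer ROI ids, `1..n`, unique and contiguous.
#' @param name character ROI names.
#' @param rsn character RSN label per ROI (one of [RSN_LABELS] by convention,
#'   but any consistent labelling is accepted).
#' @param x,y,z numeric MNI centroid coordinates (mm).
#' @return A `data.frame` of class `riccifc_atlas` with columns
#'   `roi_id`, `name`, `rsn`, `x`, `y`, `z`.
#' @export
atlas_table <- function(roi_id, name, rsn, x, y, z) {
  at <- data.frame(roi_id = as.integer(roi_id), name = as.character(name),
                   rsn = as.character(rsn), x = as.numeric(x),
                   y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_atlas(at)
  class(at) <- c("riccifc_atlas", "data.frame")
  at
}

validate_atlas <- function(at) {
  need <- c("roi_id", "name", "rsn", "x", "y", "z")
  miss <- setdiff(need, names(at))
  if (length(miss))
    stop_input("atlas is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(at$roi_id))
    stop_input("atlas has duplicate roi_id: %s",
               paste(unique(at$roi_id[duplicated(at$roi_id)]), collapse = ", "))
  if (!identical(sort(as.integer(at$roi_id)), seq_len(nrow(at))))
    stop_input("atlas roi_id must be contiguous 1..%d", nrow(at))
  if (anyNA(at$rsn) || any(!nzchar(at$rsn)))
    stop_input("every ROI needs exactly one non-empty RSN label")
  invisible(at)
}

#' Read an atlas TSV
#'
#' Expects tab-separated columns `roi_id`, `name`, `rsn`, `x`, `y`, `z`.
#'
#' @param path file path.
#' @return A validated [atlas_table()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop_input("atlas file not found: %s", path)
  at <- read.delim(path, stringsAsFactors = FALSE)
  atlas_table(at$roi_id, at$name, at$rsn, at$x, at$y, at$z)
}

#' Write an atlas TSV
#'
#' @param atlas an [atlas_table()].
#' @param path output file path.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic stand-in for a 200-ROI parcellation table
#'
#' Builds an atlas with the structure of the 200-ROI, 7-network Schaefer
#' parcellation: 100 ROIs per hemisphere, each assigned to one of the seven
#' RSNs with realistic per-network sizes, and pseudo-random MNI centroids in
#' hemisphere-appropriate coordinate ranges.  The table is entirely synthetic
#' (names, block sizes and coordinates are generated, not copied from the
#' published parcellation); it exists so that atlas-dependent plumbing can be
#' exercised without distributing third-party data.
#'
#' @param n_rois even positive integer, total number of ROIs (default 200).
#' @param seed integer seed controlling the centroid draw.
#' @return An [atlas_table()].
#' @export
synthetic_atlas <- function(n_rois = 200, seed = 2026) {
  if (n_rois < 14 || n_rois %% 2 != 0)
    stop_input("n_rois must be an even integer >= 14, got %s", n_rois)
  per_hemi <- n_rois / 2
  # per-network shares loosely matching the 7-network parcellation
  share <- c(Vis = 0.155, SomMot = 0.17, DorsAttn = 0.13, SalVentAttn = 0.12,
             Limbic = 0.065, Cont = 0.13, Default = 0.23)
  sizes <- floor(share * per_hemi)
  while (sum(sizes) < per_hemi) sizes[which.max(share * per_hemi - sizes)] <-
      sizes[which.max(share * per_hemi - sizes)] + 1
  rsn_h <- rep(names(sizes), times = sizes)
  with_seed(seed, {
    mk <- function(hemi, sign) {
      idx <- stats::ave(seq_along(rsn_h), rsn_h, FUN = seq_along)
      data.frame(
        name = sprintf("%s_%s_%d", hemi, rsn_h, idx),
        rsn = rsn_h,
        x = sign * runif(per_hemi, 5, 65),
        y = runif(per_hemi, -100, 65),
        z = runif(per_hemi, -40, 75),
        stringsAsFactors = FALSE)
    }
    lh <- mk("LH", -1)
    rh <- mk("RH", +1)
  })
  both <- rbind(lh, rh)
  atlas_table(seq_len(n_rois), both$name, both$rsn,
              round(both$x), round(both$y), round(both$z))
}
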