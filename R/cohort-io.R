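# On-disk cohort layout: one 8-bit grayscale PNG per B-scan plus a
# manifest.csv (image_id, patient_id, volume_id, label, relative_path).
# The same manifest schema is how any real OCT archive would be ingested;
# downstream code never assumes phantom origin.

#' Write a cohort to disk
#'
#' Writes one 8-bit grayscale PNG per B-scan (quantizing the `[0, 1]` float
#' intensities to 256 levels) and a `manifest.csv` with columns `image_id`,
#' `patient_id`, `volume_id`, `label`, `relative_path`.
#'
#' @param cohort An `oct_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oct_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  rel <- file.path("images", paste0(m$image_id, ".png"))
  for (i in seq_len(nrow(m))) {
    png::writePNG(cohort$images[[m$image_id[i]]], file.path(dir, rel[i]))
  }
  man <- cbind(m, relative_path = rel)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Ingests a cohort from the on-disk layout written by [write_cohort()] (or
#' produced by any adapter emitting the same manifest schema): grayscale
#' images plus a manifest table with one row per B-scan. Labels may be any of
#' the three classes or `UNLABELED`; the patient/volume hierarchy is
#' validated on load.
#'
#' @param manifest_path Path to a `manifest.csv` with columns `image_id`,
#'   `patient_id`, `volume_id`, `label`, `relative_path` (relative to the
#'   manifest's directory).
#' @return An `oct_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("image_id", "patient_id", "volume_id", "label", "relative_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  images <- stats::setNames(lapply(man$relative_path, function(p) {
    img <- png::readPNG(file.path(base, p))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }), man$image_id)
  new_cohort(images, man[, setdiff(names(man), "relative_path")])
}
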