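#' Age-stratified spatial prevalence of atrophy on the common grid
#'
#' Pools binarized superpixel atrophy maps (the `>= 0.5` layer) from many
#' exams into age strata and computes, per superpixel location, the
#' percentage of examinations showing atrophy there. Because every map is
#' anchored at the fovea with the ONH at (20, 0), locations are directly
#' comparable across eyes. Narrow-field exams simply contribute no
#' observation at peripheral locations. Multiple exams from one eye may
#' fall in one stratum (matching the pooled-examination design);
#' locations observed in fewer than `min_exams` exams are censored.
#'
#' @param maps List of [compute_atrophy_map()] results.
#' @param ages Numeric vector of ages at examination, one per map
#'   (defaults to the maps' `age_years` attributes).
#' @param breaks Stratum boundaries in years; strata are
#'   `(-Inf, b1], (b1, b2], ..., (bk, Inf)` (upper-inclusive).
#' @param min_exams Censoring threshold on per-location exam counts.
#' @return Object of class `age_stratum_maps`: data.frame with columns
#'   `stratum`, `gx`, `gy`, `n_exams`, `n_atrophic`, `percent` (NA where
#'   censored), `censored`.
#' @export
stratify_and_prevalence <- function(maps, ages = NULL,
                                    breaks = c(55, 60, 65, 70),
                                    min_exams = 4) {
  stopifnot(length(maps) >= 1, min_exams >= 1)
  if (is.null(ages)) {
    ages <- vapply(maps, function(m) attr(m, "age_years"), numeric(1))
  }
  if (length(ages) != length(maps) || anyNA(ages)) {
    stop("one age per map is required", call. = FALSE)
  }
  labels <- stratum_labels(breaks)
  strata <- cut(ages, c(-Inf, breaks, Inf), labels = labels, right = TRUE)
  pooled <- do.call(rbind, lapply(seq_along(maps), function(i) {
    m <- as.data.frame(maps[[i]])
    data.frame(stratum = strata[i], gx = m$gx, gy = m$gy,
               atrophic = m$atrophic)
  }))
  agg_n <- stats::aggregate(atrophic ~ stratum + gx + gy, pooled, length, drop = TRUE)
  agg_a <- stats::aggregate(atrophic ~ stratum + gx + gy, pooled, sum, drop = TRUE)
  out <- data.frame(stratum = agg_n$stratum, gx = agg_n$gx, gy = agg_n$gy,
                    n_exams = agg_n$atrophic, n_atrophic = agg_a$atrophic)
  out$censored <- out$n_exams < min_exams
  out$percent <- ifelse(out$censored, NA_real_, 100 * out$n_atrophic / out$n_exams)
  out <- out[order(out$stratum, out$gx, out$gy), ]
  rownames(out) <- NULL
  structure(out[, c("stratum", "gx", "gy", "n_exams", "n_atrophic",
                    "percent", "censored")],
            class = c("age_stratum_maps", "data.frame"),
            breaks = breaks, min_exams = min_exams)
}

stratum_labels <- function(breaks) {
  k <- length(breaks)
  c(sprintf("<=%g", breaks[1]),
    if (k > 1) sprintf("%g-%g", breaks[-k], breaks[-1]),
    sprintf(">%g", breaks[k]))
}

#' Export age-stratum prevalence maps
#'
#' Writes the long-format CSV (`stratum, gx, gy, n_exams, n_atrophic,
#' percent, censored`) and optionally a grayscale PNG heat-map per stratum
#' (percent scaled to 0-1, censored locations black, fovea marked).
#'
#' @param strata An [stratify_and_prevalence()] result.
#' @param path CSV output path.
#' @param png_dir Optional directory for rendered PNG heat-maps.
#' @return `path`, invisibly.
#' @export
export_heatmaps <- function(strata, path, png_dir = NULL) {
  stopifnot(inherits(strata, "age_stratum_maps"))
  utils::write.csv(as.data.frame(strata), path, row.names = FALSE)
  if (!is.null(png_dir)) {
    dir.create(png_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in unique(strata$stratum)) {
      sub <- strata[strata$stratum == s & !strata$censored, ]
      if (!nrow(sub)) next
      gx <- sub$gx - min(sub$gx); gy <- sub$gy - min(sub$gy)
      img <- matrix(0, max(gy) + 1, max(gx) + 1)
      img[cbind(gy + 1, gx + 1)] <- sub$percent / 100
      fx <- -min(sub$gx) + 1; fy <- -min(sub$gy) + 1
      if (fy >= 1 && fy <= nrow(img) && fx >= 1 && fx <= ncol(img)) {
        img[fy, fx] <- 1  # fovea marker
      }
      fname <- file.path(png_dir, paste0("stratum_", gsub("[^0-9A-Za-z=<>-]", "_", s), ".png"))
      png::writePNG(img, fname)
    }
  }
  invisible(path)
}
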