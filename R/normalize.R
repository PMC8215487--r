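#' Local background subtraction
#'
#' Subtracts each spot's local background from its raw intensity, flooring
#' at zero (arbitrary-unit intensities are non-negative by construction).
#'
#' @param raw_intensity,local_background non-negative numeric vectors.
#' @return background-corrected intensities.
#' @examples
#' subtract_background(100, 20)  # 80
#' subtract_background(15, 20)   # 0 (clipped)
#' @export
subtract_background <- function(raw_intensity, local_background) {
  if (any(raw_intensity < 0, na.rm = TRUE)) {
    stop("`raw_intensity` must be >= 0", call. = FALSE)
  }
  if (any(local_background < 0, na.rm = TRUE)) {
    stop("`local_background` must be >= 0", call. = FALSE)
  }
  pmax(raw_intensity - local_background, 0)
}

#' Negative-control subtraction
#'
#' Removes the antibody-independent signal measured on the matched
#' negative-control slide (secondary antibody only). Values and controls are
#' matched elementwise — callers align them by spot coordinates; within
#' [run_normalization()] the match is on
#' (sample, antibody, print concentration, replicate).
#'
#' @param values background-corrected intensities.
#' @param negctrl_values matched negative-control intensities (same length,
#'   or length 1 for a shared per-sample mean).
#' @return corrected intensities, floored at 0.
#' @export
subtract_negative_control <- function(values, negctrl_values) {
  if (length(negctrl_values) != 1L && length(negctrl_values) != length(values)) {
    stop(sprintf("negative-control values (%d) do not match sample values (%d)",
                 length(negctrl_values), length(values)), call. = FALSE)
  }
  pmax(values - negctrl_values, 0)
}

#' Replicate averaging
#'
#' Arithmetic mean of the finite technical replicates; missing replicates
#' are excluded. Returns `NA` (an explicit missing marker, not an error)
#' when no replicate is usable.
#'
#' @param values replicate intensities, possibly containing `NA`.
#' @return the mean, with attribute `replicate_count` giving the number of
#'   replicates used.
#' @export
average_replicates <- function(values) {
  ok <- is.finite(values)
  out <- if (any(ok)) mean(values[ok]) else NA_real_
  structure(out, replicate_count = sum(ok))
}

#' Total-protein (Sypro) normalization
#'
#' Divides an intensity by the sample's relative total-protein loading,
#' `sypro_value / sypro_reference`, where the reference is by convention the
#' cohort median Sypro signal. A sample at median loading is unchanged.
#' Non-positive Sypro values yield a missing marker with a warning.
#'
#' @param value intensity in A.U.
#' @param sypro_value the sample's total-protein channel signal.
#' @param sypro_reference cohort reference (median) Sypro signal.
#' @return normalized intensity, or `NA` where Sypro is unusable.
#' @export
normalize_total_protein <- function(value, sypro_value, sypro_reference) {
  assert_scalar_number(sypro_reference, "sypro_reference")
  if (sypro_reference <= 0) stop("`sypro_reference` must be > 0", call. = FALSE)
  bad <- !is.finite(sypro_value) | sypro_value <= 0
  if (any(bad)) {
    warning(sprintf("%d sample(s) with non-positive Sypro signal set to missing",
                    sum(bad)), call. = FALSE)
  }
  out <- value / (sypro_value / sypro_reference)
  out[bad] <- NA_real_
  out
}

aggregate_channel <- function(df, value_col = "corrected") {
  # replicate-average a per-spot table down to (sample, antibody, conc)
  by <- list(sample_id = df$sample_id, antibody_id = df$antibody_id,
             print_conc_mg_ml = df$print_conc_mg_ml)
  out <- stats::aggregate(df[[value_col]], by,
                          function(v) as.numeric(average_replicates(v)))
  names(out)[4L] <- "value"
  out$replicate_count <- stats::aggregate(df[[value_col]], by,
                                          function(v) sum(is.finite(v)))$x
  out
}

#' Run the full RPPA normalization chain
#'
#' Applies, in order: local background subtraction, negative-control
#' subtraction, replicate averaging, and total-protein (Sypro)
#' normalization, then selects one print concentration (default 0.5 mg/ml)
#' to form the samples-by-endpoints matrix of normalized intensities in
#' arbitrary units (A.U.).
#'
#' @param spots a spot table (see [generate_slide()] / [read_spot_table()]).
#' @param print_conc print concentration to analyze (default 0.5 mg/ml).
#' @param background,negative_control,total_protein logical switches for the
#'   individual correction steps (all `TRUE` by default; steps whose control
#'   channel is absent from `spots` must be disabled explicitly).
#' @param negctrl_method `"spot"` matches negative-control values per spot
#'   (sample, antibody, concentration, replicate); `"antibody_mean"`
#'   subtracts the per-(sample, antibody, concentration) mean control value.
#' @return a numeric matrix (samples x endpoints) of class `rppa_matrix`
#'   with a `"provenance"` attribute recording every applied step and
#'   parameter.
#' @examples
#' lay <- assay_layout(c("EpCAM", "PSA"), sprintf("S%d", 1:4))
#' coh <- cohort_spec(c(HD = 2, PCa = 2), noise_cv = 0.05, seed = 3)
#' mat <- run_normalization(generate_slide(lay, coh))
#' dim(mat)  # 4 x 2
#' @export
run_normalization <- function(spots, print_conc = 0.5,
                              background = TRUE,
                              negative_control = TRUE,
                              total_protein = TRUE,
                              negctrl_method = c("spot", "antibody_mean")) {
  stopifnot(is.data.frame(spots))
  negctrl_method <- match.arg(negctrl_method)
  ab <- spots[spots$channel == "antibody", , drop = FALSE]
  if (nrow(ab) == 0) stop("spot table contains no antibody-channel rows", call. = FALSE)
  if (!print_conc %in% ab$print_conc_mg_ml) {
    stop(sprintf("print concentration %s absent; available: %s", format(print_conc),
                 paste(sort(unique(ab$print_conc_mg_ml)), collapse = ", ")),
         call. = FALSE)
  }

  # 1. local background subtraction
  ab$corrected <- if (background) {
    subtract_background(ab$raw_intensity, ab$local_background)
  } else ab$raw_intensity

  # 2. negative-control subtraction (per matched spot by default)
  if (negative_control) {
    nc <- spots[spots$channel == "negative_control", , drop = FALSE]
    if (nrow(nc) == 0) {
      stop("negative-control channel required but absent (set negative_control = FALSE to skip)",
           call. = FALSE)
    }
    nc$corrected <- if (background) {
      subtract_background(nc$raw_intensity, nc$local_background)
    } else nc$raw_intensity
    key <- function(d) paste(d$sample_id, d$antibody_id, d$print_conc_mg_ml,
                             d$replicate_idx, sep = "\r")
    if (negctrl_method == "spot") {
      idx <- match(key(ab), key(nc))
      if (anyNA(idx)) {
        orphan <- ab[which(is.na(idx))[1L], ]
        stop(sprintf("no negative-control spot matches sample %s / %s / %s mg/ml / rep %d",
                     orphan$sample_id, orphan$antibody_id,
                     format(orphan$print_conc_mg_ml), orphan$replicate_idx),
             call. = FALSE)
      }
      ab$corrected <- subtract_negative_control(ab$corrected, nc$corrected[idx])
    } else {
      gkey <- function(d) paste(d$sample_id, d$antibody_id, d$print_conc_mg_ml,
                                sep = "\r")
      ncm <- tapply(nc$corrected, gkey(nc), mean)
      idx <- match(gkey(ab), names(ncm))
      if (anyNA(idx)) {
        orphan <- ab[which(is.na(idx))[1L], ]
        stop(sprintf("no negative-control spots for sample %s / %s",
                     orphan$sample_id, orphan$antibody_id), call. = FALSE)
      }
      ab$corrected <- subtract_negative_control(ab$corrected, as.numeric(ncm[idx]))
    }
  }

  # 3. replicate averaging
  agg <- aggregate_channel(ab)

  # 4. total-protein normalization against the cohort-median Sypro signal
  sypro_ref <- NA_real_
  if (total_protein) {
    sy <- spots[spots$channel == "total_protein", , drop = FALSE]
    if (nrow(sy) == 0) {
      stop("total-protein channel required but absent (set total_protein = FALSE to skip)",
           call. = FALSE)
    }
    sy$corrected <- if (background) {
      subtract_background(sy$raw_intensity, sy$local_background)
    } else sy$raw_intensity
    skey <- paste(sy$sample_id, sy$print_conc_mg_ml, sep = "\r")
    sy_mean <- tapply(sy$corrected, skey, function(v) as.numeric(average_replicates(v)))
    idx <- match(paste(agg$sample_id, agg$print_conc_mg_ml, sep = "\r"),
                 names(sy_mean))
    if (anyNA(idx)) {
      orphan <- agg[which(is.na(idx))[1L], ]
      stop(sprintf("no total-protein spots for sample %s at %s mg/ml",
                   orphan$sample_id, format(orphan$print_conc_mg_ml)),
           call. = FALSE)
    }
    sy_sample <- as.numeric(sy_mean[idx])
    # reference computed per print concentration over usable samples
    for (pc in unique(agg$print_conc_mg_ml)) {
      sel <- agg$print_conc_mg_ml == pc
      ref <- stats::median(sy_sample[sel][sy_sample[sel] > 0], na.rm = TRUE)
      sypro_ref <- ref
      agg$value[sel] <- normalize_total_protein(agg$value[sel],
                                                sy_sample[sel], ref)
    }
  }

  sel <- agg$print_conc_mg_ml == print_conc
  agg <- agg[sel, , drop = FALSE]
  samples <- unique(ab$sample_id)
  endpoints <- unique(ab$antibody_id)
  mat <- matrix(NA_real_, length(samples), length(endpoints),
                dimnames = list(samples, endpoints))
  mat[cbind(match(agg$sample_id, samples), match(agg$antibody_id, endpoints))] <-
    agg$value

  structure(mat, class = c("rppa_matrix", "matrix", "array"),
            provenance = list(
              steps = c(background = background,
                        negative_control = negative_control,
                        replicate_averaging = TRUE,
                        total_protein = total_protein),
              negctrl_method = if (negative_control) negctrl_method else NA,
              print_conc_mg_ml = print_conc,
              sypro_reference = sypro_ref,
              n_spots_in = nrow(ab)))
}
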