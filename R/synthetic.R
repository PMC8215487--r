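#' Describe an RPPA slide layout
#'
#' Captures the geometry of the printed array: which antibodies (endpoints)
#' are probed, which samples are printed, how many technical replicate spots
#' each sample gets, at which total-protein print concentrations, and whether
#' a total-protein (Sypro) channel and a secondary-antibody-only
#' negative-control slide are included. Defaults reflect the common assay
#' setup: triplicate spots at 0.5 and 0.125 mg/ml with both control channels.
#'
#' @param antibodies character vector of endpoint identifiers.
#' @param samples character vector of sample identifiers.
#' @param replicates_per_spot technical replicates per printed sample
#'   (default 3).
#' @param print_concentrations total-protein print concentrations in mg/ml
#'   (default `c(0.5, 0.125)`).
#' @param reference_curve_points number of points in reference dilution
#'   curves (default 10).
#' @param has_negative_control_slide,has_total_protein_channel logical;
#'   include the corresponding control channels.
#' @return an object of class `assay_layout`.
#' @export
assay_layout <- function(antibodies, samples,
                         replicates_per_spot = 3L,
                         print_concentrations = c(0.5, 0.125),
                         reference_curve_points = 10L,
                         has_negative_control_slide = TRUE,
                         has_total_protein_channel = TRUE) {
  if (length(antibodies) == 0) stop("`antibodies` must not be empty", call. = FALSE)
  if (length(samples) == 0) stop("`samples` must not be empty", call. = FALSE)
  if (anyDuplicated(antibodies)) stop("duplicated antibody identifiers", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers", call. = FALSE)
  assert_scalar_number(replicates_per_spot, "replicates_per_spot", min = 1)
  if (any(print_concentrations <= 0)) {
    stop("`print_concentrations` must all be > 0", call. = FALSE)
  }
  assert_scalar_number(reference_curve_points, "reference_curve_points", min = 2)
  structure(
    list(antibodies = as.character(antibodies),
         samples = as.character(samples),
         replicates_per_spot = as.integer(replicates_per_spot),
         print_concentrations = as.numeric(print_concentrations),
         reference_curve_points = as.integer(reference_curve_points),
         has_negative_control_slide = isTRUE(has_negative_control_slide),
         has_total_protein_channel = isTRUE(has_total_protein_channel)),
    class = "assay_layout")
}

#' Describe a synthetic cohort
#'
#' Defines the sample groups printed on a synthetic slide and the
#' multiplicative effects each group imposes on selected endpoints, together
#' with the spot-level noise model. Spot noise is multiplicative log-normal
#' with the given coefficient of variation; each sample additionally carries
#' a total-protein loading multiplier (shared between its antibody and Sypro
#' channels) drawn with CV `loading_cv`, which defaults to `noise_cv` so
#' that a noiseless cohort is exactly deterministic.
#'
#' @param groups named integer vector: group label -> sample count.
#' @param effects optional data.frame with columns `endpoint`, `group`,
#'   `effect` giving multiplicative effect sizes (relative to baseline) for
#'   specific (endpoint, group) pairs; unlisted pairs have effect 1.
#' @param noise_cv coefficient of variation of multiplicative spot noise.
#' @param loading_cv CV of the per-sample loading multiplier (default
#'   `noise_cv`).
#' @param biological_cv CV of the per-(sample, endpoint) biological
#'   multiplier, shared across a sample's replicates and print
#'   concentrations (default 0). This models inter-individual variability
#'   of true marker levels — the component that does not average away over
#'   technical replicates.
#' @param baseline_intensity baseline specific signal, arbitrary units.
#' @param background_level mean local background intensity (A.U.).
#' @param negctrl_level mean antibody-independent (secondary-antibody-only)
#'   signal, present additively in the antibody channel and measured by the
#'   negative-control slide.
#' @param sypro_baseline baseline of the total-protein channel (A.U.).
#' @param seed integer seed governing all randomness of the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, effects = NULL, noise_cv = 0.1,
                        loading_cv = noise_cv,
                        biological_cv = 0,
                        baseline_intensity = 1000,
                        background_level = 50,
                        negctrl_level = 20,
                        sypro_baseline = 5000,
                        seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named vector (group label -> sample count)", call. = FALSE)
  }
  if (any(groups < 0)) stop("group sample counts must be >= 0", call. = FALSE)
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  assert_scalar_number(loading_cv, "loading_cv", min = 0)
  assert_scalar_number(biological_cv, "biological_cv", min = 0)
  assert_scalar_number(baseline_intensity, "baseline_intensity", min = 0)
  assert_scalar_number(background_level, "background_level", min = 0)
  assert_scalar_number(negctrl_level, "negctrl_level", min = 0)
  assert_scalar_number(sypro_baseline, "sypro_baseline", min = 0)
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("endpoint", "group", "effect") %in% names(effects)))
    if (any(effects$effect <= 0)) stop("effect sizes must be > 0", call. = FALSE)
  }
  structure(
    list(groups = groups, effects = effects, noise_cv = noise_cv,
         loading_cv = loading_cv, biological_cv = biological_cv,
         baseline_intensity = baseline_intensity,
         background_level = background_level, negctrl_level = negctrl_level,
         sypro_baseline = sypro_baseline, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Sample annotation implied by a cohort specification
#'
#' Builds the clinical annotation table matched to [generate_slide()]:
#' sample id, group, and placeholder clinical covariates (PSA, Gleason,
#' pTNM, recurrence, follow-up) left missing. Callers can fill covariates
#' afterwards or use [simulate_annotation()] for a populated version.
#'
#' @param cohort a [cohort_spec()].
#' @return data.frame with one row per sample.
#' @export
cohort_samples <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  grp <- rep(names(cohort$groups), times = cohort$groups)
  ids <- unlist(lapply(names(cohort$groups), function(g) {
    n <- cohort$groups[[g]]
    if (n == 0) character(0) else sprintf("%s_%02d", g, seq_len(n))
  }), use.names = FALSE)
  data.frame(sample_id = ids, group = grp,
             psa_ng_ml = NA_real_, gleason = NA_character_,
             ptnm = NA_character_, recurrent = NA_integer_,
             followup_years = NA_real_, stringsAsFactors = FALSE)
}

effect_for <- function(cohort, endpoint, group) {
  ef <- cohort$effects
  if (is.null(ef)) return(1)
  hit <- ef$endpoint == endpoint & ef$group == group
  if (any(hit)) ef$effect[which(hit)[1L]] else 1
}

#' Generate a synthetic spot-level RPPA table
#'
#' Emulates one print run: each sample is printed in
#' `replicates_per_spot` technical spots at every print concentration on one
#' slide per antibody, together with a matched total-protein (Sypro) channel
#' and a negative-control slide of identical geometry carrying only
#' antibody-independent signal.
#'
#' The expected specific signal of a spot is
#' `baseline_intensity * effect(endpoint, group) * (conc / max conc)`,
#' multiplied by the sample's loading factor and log-normal spot noise with
#' CV `noise_cv`. The recorded `raw_intensity` adds the local background and
#' the nonspecific (negative-control-level) component, which the
#' normalization chain removes again.
#'
#' @param layout an [assay_layout()].
#' @param cohort a [cohort_spec()]; total sample count must match
#'   `length(layout$samples)` or `layout` samples are taken from
#'   [cohort_samples()].
#' @return a `data.frame` of class `spot_table` with columns `slide_id`,
#'   `channel`, `antibody_id`, `sample_id`, `print_conc_mg_ml`,
#'   `replicate_idx`, `raw_intensity`, `local_background`, plus a
#'   `"samples"` attribute holding the sample annotation.
#' @examples
#' lay <- assay_layout(c("EpCAM", "PSA"), sprintf("S%d", 1:3))
#' coh <- cohort_spec(c(HD = 2, PCa = 1), noise_cv = 0, seed = 7)
#' spots <- generate_slide(lay, coh)
#' nrow(spots[spots$channel == "antibody", ])  # 2 x 3 x 3 x 2 = 36
#' @export
generate_slide <- function(layout, cohort) {
  stopifnot(inherits(layout, "assay_layout"), inherits(cohort, "cohort_spec"))
  ann <- cohort_samples(cohort)
  if (length(layout$samples) != nrow(ann)) {
    stop(sprintf("layout has %d samples but cohort defines %d",
                 length(layout$samples), nrow(ann)), call. = FALSE)
  }
  ann$sample_id <- layout$samples  # layout ids take precedence
  n_s <- nrow(ann)

  set.seed(derive_seed(cohort$seed, "slide"))
  loading <- lognormal_factor(n_s, cohort$loading_cv)
  names(loading) <- ann$sample_id
  # biological multiplier: one draw per (sample, endpoint), shared across
  # replicates and print concentrations
  bio <- matrix(lognormal_factor(n_s * length(layout$antibodies),
                                 cohort$biological_cv),
                nrow = n_s,
                dimnames = list(ann$sample_id, layout$antibodies))

  conc_scale <- layout$print_concentrations / max(layout$print_concentrations)

  grid <- expand.grid(replicate_idx = seq_len(layout$replicates_per_spot),
                      sample_i = seq_len(n_s),
                      conc_i = seq_along(layout$print_concentrations),
                      antibody_id = layout$antibodies,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  eff <- mapply(function(ab, si) effect_for(cohort, ab, ann$group[si]),
                grid$antibody_id, grid$sample_i)
  signal <- cohort$baseline_intensity * eff *
    bio[cbind(grid$sample_i, match(grid$antibody_id, layout$antibodies))] *
    conc_scale[grid$conc_i] * loading[grid$sample_i] *
    lognormal_factor(n, cohort$noise_cv)
  bkg <- cohort$background_level * lognormal_factor(n, cohort$noise_cv)
  nonspec <- cohort$negctrl_level * lognormal_factor(n, cohort$noise_cv)

  ab_tab <- data.frame(
    slide_id = paste0("slide_", grid$antibody_id),
    channel = "antibody",
    antibody_id = grid$antibody_id,
    sample_id = ann$sample_id[grid$sample_i],
    print_conc_mg_ml = layout$print_concentrations[grid$conc_i],
    replicate_idx = grid$replicate_idx,
    raw_intensity = bkg + nonspec + signal,
    local_background = bkg,
    stringsAsFactors = FALSE)

  out <- ab_tab
  if (layout$has_negative_control_slide) {
    nc_sig <- cohort$negctrl_level * lognormal_factor(n, cohort$noise_cv)
    nc_bkg <- cohort$background_level * lognormal_factor(n, cohort$noise_cv)
    nc <- ab_tab
    nc$slide_id <- "slide_negctrl"
    nc$channel <- "negative_control"
    nc$raw_intensity <- nc_bkg + nc_sig
    nc$local_background <- nc_bkg
    out <- rbind(out, nc)
  }
  if (layout$has_total_protein_channel) {
    m <- nrow(grid) / length(layout$antibodies)  # sypro printed once, not per antibody
    sg <- grid[grid$antibody_id == layout$antibodies[1L], , drop = FALSE]
    sy_bkg <- cohort$background_level * lognormal_factor(m, cohort$noise_cv)
    sy_sig <- cohort$sypro_baseline * conc_scale[sg$conc_i] *
      loading[sg$sample_i] * lognormal_factor(m, cohort$noise_cv)
    sy <- data.frame(
      slide_id = "slide_sypro",
      channel = "total_protein",
      antibody_id = NA_character_,
      sample_id = ann$sample_id[sg$sample_i],
      print_conc_mg_ml = layout$print_concentrations[sg$conc_i],
      replicate_idx = sg$replicate_idx,
      raw_intensity = sy_bkg + sy_sig,
      local_background = sy_bkg,
      stringsAsFactors = FALSE)
    out <- rbind(out, sy)
  }
  rownames(out) <- NULL
  attr(out, "samples") <- ann
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Describe a positive/negative EV mixture series
#'
#' @param fractions percentages (0-100) of the positive EV source.
#' @param positive_level,negative_level expected intensities (A.U.) of the
#'   pure positive and pure negative sources.
#' @param noise_cv coefficient of variation of multiplicative spot noise.
#' @param seed integer seed.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(fractions, positive_level, negative_level,
                         noise_cv = 0.1, seed = 1L) {
  if (any(fractions < 0 | fractions > 100)) {
    stop("`fractions` must lie in [0, 100]", call. = FALSE)
  }
  assert_scalar_number(positive_level, "positive_level", min = 0)
  assert_scalar_number(negative_level, "negative_level", min = 0)
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  structure(list(fractions = as.numeric(fractions),
                 positive_level = positive_level,
                 negative_level = negative_level,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate a synthetic EV mixture dilution series
#'
#' Emulates printing scaling mixtures of a marker-positive and a
#' marker-negative EV source: the expected normalized intensity at positive
#' fraction f (in percent) is
#' `negative_level + (positive_level - negative_level) * f / 100`, with
#' replicate spots carrying multiplicative log-normal noise.
#'
#' @param spec a [mixture_spec()].
#' @param layout an [assay_layout()]; only `replicates_per_spot` is used.
#' @return a [mixture_series()] object (fractions, replicate intensity
#'   matrix, background statistics from the 0%-fraction replicates when
#'   present).
#' @export
generate_mixture_series <- function(spec, layout) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(layout, "assay_layout"))
  reps <- layout$replicates_per_spot
  set.seed(derive_seed(spec$seed, "mixture"))
  expected <- spec$negative_level +
    (spec$positive_level - spec$negative_level) * spec$fractions / 100
  intens <- vapply(expected,
                   function(mu) mu * lognormal_factor(reps, spec$noise_cv),
                   numeric(reps))
  intens <- matrix(intens, nrow = reps)  # reps x fractions
  mixture_series(fractions = spec$fractions,
                 intensities = t(intens))
}

#' Construct a mixture series container
#'
#' @param fractions percentages of the positive source; sorted ascending on
#'   construction.
#' @param intensities matrix of replicate intensities, one row per fraction.
#' @param background_stats optional list `list(mean =, sd =, n =)`; when
#'   omitted it is derived from the 0%-fraction replicates.
#' @return object of class `mixture_series`.
#' @export
mixture_series <- function(fractions, intensities, background_stats = NULL) {
  intensities <- as.matrix(intensities)
  if (length(fractions) != nrow(intensities)) {
    stop("one intensity row required per fraction", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 100)) {
    stop("`fractions` must lie in [0, 100]", call. = FALSE)
  }
  ord <- order(fractions)
  fractions <- fractions[ord]
  intensities <- intensities[ord, , drop = FALSE]
  if (is.null(background_stats)) {
    if (any(fractions == 0)) {
      bg <- as.numeric(intensities[fractions == 0, , drop = FALSE])
      background_stats <- list(mean = mean(bg), sd = stats::sd(bg),
                               n = length(bg))
      if (length(bg) == 1L) background_stats$sd <- 0
    }
  }
  structure(list(fractions = fractions, intensities = intensities,
                 background_stats = background_stats),
            class = "mixture_series")
}

#' Generate a synthetic-peptide reference dilution curve
#'
#' Emulates printing a synthetic peptide in a dilution series: replicate
#' log10 intensities follow
#' `log10(intensity) = intercept + slope * log10(amount) + N(0, noise_sd)`.
#'
#' @param analyte endpoint identifier the curve calibrates.
#' @param amounts known peptide amounts in pg; all > 0, at least two
#'   distinct values.
#' @param slope,intercept parameters of the log10-linear response.
#' @param noise_sd Gaussian noise SD in log10 units.
#' @param replicates technical replicates per point (default 3).
#' @param seed integer seed.
#' @return a `reference_curve_data` data.frame with columns `amount_pg`,
#'   `replicate_idx`, `intensity`, and an `"analyte"` attribute.
#' @export
generate_reference_curve <- function(analyte, amounts, slope, intercept,
                                     noise_sd = 0, replicates = 3L,
                                     seed = 1L) {
  if (any(amounts <= 0)) stop("`amounts` must be > 0 (log undefined)", call. = FALSE)
  if (length(unique(amounts)) < 2) {
    stop("at least 2 distinct amounts required", call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(replicates, "replicates", min = 1)
  set.seed(derive_seed(seed, paste0("refcurve:", analyte)))
  amount <- rep(as.numeric(amounts), each = replicates)
  log_int <- intercept + slope * log10(amount) +
    stats::rnorm(length(amount), 0, noise_sd)
  out <- data.frame(amount_pg = amount,
                    replicate_idx = rep(seq_len(replicates), length(amounts)),
                    intensity = 10^log_int,
                    stringsAsFactors = FALSE)
  attr(out, "analyte") <- analyte
  class(out) <- c("reference_curve_data", "data.frame")
  out
}
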