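# Quantitative arithmetic of the two-step L-Phe -> trans-cinnamic acid ->
# styrene pathway: stoichiometric mass-concentration interconversion (1:1:1
# molar ratios), substrate yields, annualized projections, and initial-rate
# estimation from bioconversion time courses.

#' Pathway stoichiometry for the Phe -> tCA -> styrene route
#'
#' One mole of L-phenylalanine deaminates to one mole of trans-cinnamic acid,
#' which decarboxylates to one mole of styrene, so mass concentrations
#' interconvert by molar-mass ratios alone. Default molar masses (g/mol):
#' L-Phe 165.19, tCA 148.16, styrene 104.15.
#'
#' @param molar_mass Named numeric vector of molar masses (g/mol).
#' @return An object of class `pathway_stoichiometry`.
#' @export
pathway_stoichiometry <- function(molar_mass = c("L-Phe" = 165.19,
                                                 "tCA" = 148.16,
                                                 "styrene" = 104.15)) {
  if (any(molar_mass <= 0) || is.null(names(molar_mass)))
    stop_input("molar masses must be positive and named")
  structure(list(molar_mass = molar_mass), class = "pathway_stoichiometry")
}

resolve_compound <- function(compound, stoich) {
  nm <- names(stoich$molar_mass)
  hit <- match(tolower(compound), tolower(nm))
  if (is.na(hit)) {
    # common aliases
    alias <- c("phe" = "l-phe", "l-phenylalanine" = "l-phe",
               "phenylalanine" = "l-phe", "trans-cinnamic acid" = "tca",
               "cinnamic acid" = "tca")
    key <- alias[tolower(compound)]
    if (!is.na(key)) hit <- match(key, tolower(nm))
  }
  if (is.na(hit))
    stop_input("unknown compound '", compound, "'; known: ",
               paste(nm, collapse = ", "))
  nm[hit]
}

#' Stoichiometric mass-concentration conversion
#'
#' Converts a mass concentration of one pathway compound into the equivalent
#' concentration of another under 1:1 molar stoichiometry:
#' `conc * M(to) / M(from)`.
#'
#' @param conc Concentration in mg/L (vectorized).
#' @param from,to Compound names.
#' @param stoich A [pathway_stoichiometry()].
#' @return Concentration of `to` in mg/L.
#' @examples
#' stoich_convert(600, "L-Phe", "styrene")  # ~378 mg/L
#' @export
stoich_convert <- function(conc, from, to,
                           stoich = pathway_stoichiometry()) {
  if (any(conc < 0)) stop_input("concentrations must be non-negative")
  from <- resolve_compound(from, stoich)
  to <- resolve_compound(to, stoich)
  conc * stoich$molar_mass[[to]] / stoich$molar_mass[[from]]
}

#' Product yield per mass of substrate
#'
#' @param product Product titer in mg/L.
#' @param substrate Substrate supplied in g/L (must be positive).
#' @return Yield in mg product per g substrate.
#' @examples
#' yield_per_substrate(221, 5)  # 44.2 mg/g
#' @export
yield_per_substrate <- function(product, substrate) {
  if (any(substrate <= 0)) stop_input("substrate must be positive")
  if (any(product < 0)) stop_input("product must be non-negative")
  product / substrate
}

#' Fraction of consumed substrate recovered as product
#'
#' Compares the product actually formed with the product expected from the
#' consumed substrate under pathway stoichiometry. Values above 1 are
#' possible only through measurement noise; they are flagged with a warning
#' and an `exceeds_unity` attribute, never clamped.
#'
#' @param substrate_consumed Consumed substrate, mg/L (> 0).
#' @param product_formed Product formed, mg/L.
#' @param from,to Compound names.
#' @param stoich A [pathway_stoichiometry()].
#' @return Conversion fraction.
#' @examples
#' conversion_fraction(100, 87, "L-Phe", "tCA")  # ~0.97
#' @export
conversion_fraction <- function(substrate_consumed, product_formed, from, to,
                                stoich = pathway_stoichiometry()) {
  if (any(substrate_consumed <= 0))
    stop_input("substrate_consumed must be positive")
  if (any(product_formed < 0))
    stop_input("product_formed must be non-negative")
  expected <- stoich_convert(substrate_consumed, from, to, stoich)
  frac <- product_formed / expected
  if (any(frac > 1)) {
    warning("conversion fraction exceeds 1 (measurement noise?)")
    attr(frac, "exceeds_unity") <- TRUE
  }
  frac
}

#' Annualize a daily production figure
#'
#' @param daily Production in tons/day (>= 0).
#' @param days Days per year (default 365).
#' @param sig_figs Significant figures for the reported figure (default 2);
#'   `NULL` for no rounding.
#' @return Tons per year.
#' @examples
#' annualize(8.5)  # 3100 t/yr at 2 significant figures
#' @export
annualize <- function(daily, days = 365L, sig_figs = 2L) {
  if (any(daily < 0)) stop_input("daily production must be non-negative")
  out <- daily * days
  if (!is.null(sig_figs)) out <- signif(out, sig_figs)
  out
}

#' Construct a bioconversion time series
#'
#' @param time_h Sampling times (hours), strictly increasing, non-negative.
#' @param conc_mg_l Concentrations (mg/L), non-negative.
#' @param analyte Compound label.
#' @return An object of class `bioconversion_series`.
#' @export
bioconversion_series <- function(time_h, conc_mg_l, analyte = "analyte") {
  if (length(time_h) != length(conc_mg_l))
    stop_input("time and concentration vectors differ in length")
  if (any(time_h < 0) || any(diff(time_h) <= 0))
    stop_input("times must be non-negative and strictly increasing")
  if (any(conc_mg_l < 0)) stop_input("concentrations must be non-negative")
  structure(list(analyte = analyte,
                 samples = data.frame(time_h = time_h,
                                      conc_mg_l = conc_mg_l)),
            class = "bioconversion_series")
}

#' @export
print.bioconversion_series <- function(x, ...) {
  cat(sprintf("<bioconversion_series> %s: %d samples over %g h\n",
              x$analyte, nrow(x$samples), max(x$samples$time_h)))
  invisible(x)
}

#' Initial rate of a bioconversion time course
#'
#' Ordinary least-squares slope of concentration versus time over the samples
#' with `time_h <= window_h` (window boundary inclusive, i.e. "the first two
#' hours" includes the 2 h sample). The sign is retained: negative slopes
#' indicate consumption.
#'
#' @param series A [bioconversion_series()].
#' @param window_h Window length in hours (default 2).
#' @return Slope in mg/L/h.
#' @examples
#' s <- bioconversion_series(c(0, 1, 2), c(100, 75, 50), "L-Phe")
#' initial_rate(s)  # -25
#' @export
initial_rate <- function(series, window_h = 2) {
  stopifnot(inherits(series, "bioconversion_series"))
  d <- series$samples[series$samples$time_h <= window_h, , drop = FALSE]
  if (nrow(d) < 2L)
    cz_stop("consenzyme_insufficient_data_error",
            "need at least 2 samples within [0, ", window_h,
            "] h; have ", nrow(d))
  unname(stats::coef(stats::lm(conc_mg_l ~ time_h, data = d))[2L])
}

#' Read bioconversion time series from CSV
#'
#' Expects columns `time_h`, `analyte`, `conc_mg_L` (one row per sample);
#' returns one series per analyte.
#'
#' @param path CSV path.
#' @return Named list of `bioconversion_series`.
#' @export
read_bioconversion_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "analyte", "conc_mg_L")
  if (!all(need %in% names(df)))
    stop_format("CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$analyte), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    bioconversion_series(d$time_h, d$conc_mg_L, analyte = d$analyte[1L])
  })
}

#' Write bioconversion time series to CSV
#' @param series A `bioconversion_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioconversion_csv <- function(series, path) {
  if (inherits(series, "bioconversion_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(time_h = s$samples$time_h, analyte = s$analyte,
               conc_mg_L = s$samples$conc_mg_l)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
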