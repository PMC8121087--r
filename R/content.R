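#' Fit a BSA standard curve
#'
#' Ordinary least squares of blank-corrected absorbance on BSA
#' concentration. Blank correction precedes the fit; the blank value is
#' stored on the curve so unknowns are corrected identically.
#'
#' @param standards data.frame with `concentration` (ug/cm^3) and
#'   `absorbance` columns; >= 3 distinct concentrations.
#' @param blank blank absorbance (scalar; a vector is averaged).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `blank`.
#' @export
fit_standard_curve <- function(standards, blank = 0) {
  if (length(unique(standards$concentration)) < 3) {
    stop("need >= 3 distinct standard concentrations")
  }
  blank <- mean(blank)
  y <- standards$absorbance - blank
  fit <- stats::lm(y ~ standards$concentration)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, blank = blank),
            class = "standard_curve")
}

#' Convert absorbance to protein content (ug/mg fresh weight)
#'
#' Inverts the standard curve:
#' `concentration = (absorbance - blank - intercept) / slope`, then
#' `content = concentration * extract_volume * dilution / fw_mg`.
#' Absorbances falling below the blank yield a negative concentration and
#' are flagged; set `clamp = TRUE` to truncate contents at 0.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param absorbance raw absorbance(s) of the unknown(s).
#' @param fw_mg fresh weight(s), mg, positive.
#' @param extract_volume extract volume, cm^3.
#' @param dilution dilution factor.
#' @param clamp truncate negative contents at 0 (default FALSE).
#' @return Numeric vector of contents with logical attribute
#'   `below_blank`.
#' @export
content_from_absorbance <- function(curve, absorbance, fw_mg,
                                    extract_volume = 0.2, dilution = 1,
                                    clamp = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("curve slope is zero")
  if (any(fw_mg <= 0)) stop("fresh weights must be positive")
  conc <- (absorbance - curve$blank - curve$intercept) / curve$slope
  content <- conc * extract_volume * dilution / fw_mg
  below <- absorbance < curve$blank + curve$intercept
  if (clamp) content <- pmax(content, 0)
  attr(content, "below_blank") <- below
  content
}

#' Recover contents from a synthetic BCA plate
#'
#' Convenience round trip for [generate_bca_plate()] output: fits the
#' standard curve on the plate's standards (blank wells averaged as the
#' blank) and inverts it for the unknown wells.
#'
#' @param plate result of [generate_bca_plate()].
#' @return data.frame with `sample_id`, `fw_mg`, `content`.
#' @export
recover_bca_contents <- function(plate) {
  wells <- plate$plate
  std <- wells[wells$well_type == "standard", ]
  blank <- mean(wells$absorbance[wells$well_type == "blank"])
  curve <- fit_standard_curve(std, blank = blank)
  unk <- wells[wells$well_type == "unknown", ]
  content <- if (nrow(unk)) {
    as.numeric(content_from_absorbance(curve, unk$absorbance, unk$fw_mg,
                                       extract_volume = plate$extract_volume,
                                       dilution = plate$dilution))
  } else numeric(0)
  out <- data.frame(sample_id = unk$sample_id, fw_mg = unk$fw_mg,
                    content = content, stringsAsFactors = FALSE)
  attr(out, "curve") <- curve
  out
}

#' Distribution-aware comparison of protein contents
#'
#' Compares contents across zone-by-treatment groups: the assumption
#' tests of [test_assumptions()] pick between a gaussian/identity GLM
#' (parametric data) and a gamma/log GLM (contents are positive,
#' right-skewed otherwise), then all pairwise group contrasts are tested
#' with single-step familywise (Tukey-style) adjustment and summarized as
#' a compact letter display: groups sharing a letter are not
#' significantly different.
#'
#' @param records data.frame with `content`, `zone`, `treatment` columns;
#'   >= 2 groups with >= 3 records each.
#' @param alpha significance level.
#' @param B_levene Levene bootstrap replicates.
#' @param seed integer seed for the assumption-test bootstrap.
#' @return List of class `content_comparison`: `family`, `glm_p`
#'   (global Wald p of the group factor), `pairwise` (glht summary
#'   frame), `letters` (named character vector), `assumptions`.
#' @export
compare_contents <- function(records, alpha = 0.05, B_levene = 1000,
                             seed = 1L) {
  records$group <- factor(paste(records$zone, records$treatment, sep = "."))
  sizes <- table(records$group)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 3)) stop("every group needs >= 3 records")
  at <- test_assumptions(records$content, records$group, alpha = alpha,
                         B_levene = B_levene, seed = seed)
  if (at$parametric) {
    family <- stats::gaussian()
    fam_name <- "gaussian"
    y <- records$content
  } else {
    fam_name <- "gamma"
    family <- stats::Gamma(link = "log")
    y <- records$content
    if (any(y <= 0)) y <- y - min(y) + 1e-6 * diff(range(y))
  }
  dat <- data.frame(y = y, group = records$group)
  fit <- stats::glm(y ~ group, data = dat, family = family)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)
  sm <- summary(glht)
  pairwise <- data.frame(contrast = names(sm$test$coefficients),
                         estimate = unname(sm$test$coefficients),
                         p_adjusted = unname(sm$test$pvalues),
                         stringsAsFactors = FALSE)
  null_dev_p <- stats::anova(fit, test = "F")$`Pr(>F)`[2]
  structure(list(family = fam_name, glm_p = null_dev_p,
                 pairwise = pairwise,
                 letters = cld$mcletters$Letters,
                 assumptions = at),
            class = "content_comparison")
}

#' Ribosomal fraction of the total protein content
#'
#' `100 * rp_content / total_content`, rounded to two significant figures
#' for reporting.
#'
#' @param rp_content ribosome-enriched fraction content, ug/mg FW.
#' @param total_content total protein content, ug/mg FW (> 0).
#' @param digits significant figures for reporting (default 2).
#' @return Percentage (numeric).
#' @export
rp_fraction <- function(rp_content, total_content, digits = 2) {
  if (any(total_content <= 0)) stop("total content must be positive")
  signif(100 * rp_content / total_content, digits)
}
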