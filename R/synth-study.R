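#' @keywords internal
ARM_LEVELS <- c("S1P", "CT_NaOH", "ZVAD", "CT_DMSO")
#' @keywords internal
CONDITION_LEVELS <- c("F", "F-T", "D2", "D6")
STAGE_LEVELS <- c("primordial", "transitional", "primary", "secondary")

# Default arm x condition mean log10(follicles/mm^2 + 1), the published
# per-group primordial-density profile of the study design this generator
# emulates: fresh tissue around 1.4-1.7 with a progressive loss over
# culture that the anti-apoptotic arms attenuate.
default_effects <- function() {
  m <- matrix(c(
    1.6012, 1.6200, 0.9070, 0.4799,   # S1P
    1.4111, 1.7764, 0.6482, 0.1584,   # CT_NaOH
    1.6209, 1.2348, 1.1145, 0.9636,   # ZVAD
    1.6609, 1.3464, 1.0350, 0.4099),  # CT_DMSO
    nrow = 4, byrow = TRUE,
    dimnames = list(ARM_LEVELS, CONDITION_LEVELS))
  m
}

#' Configuration of a simulated follicle-density study
#'
#' Describes a cryopreservation study: treatment arms (two anti-apoptotic
#' drugs and their vehicle controls), the four tissue conditions (fresh F,
#' frozen-thawed F-T, and 2 or 6 days of post-thaw culture D2/D6), 2-mm
#' cortical punches per condition, and the per-punch sectioning scheme
#' (12 density/morphology sections and 3 Ki-67 proliferation sections).
#'
#' Mean log-densities are `baseline_log_density + arm_condition_effects`;
#' each punch adds a Gaussian random fragment effect (`fragment_sd`) shared
#' by its sections, and each section a Gaussian residual (`residual_sd`),
#' all on the log10(X+1) scale. The default effects matrix encodes the
#' fresh-to-culture density decline characteristic of slow-frozen ovarian
#' cortex, with the drug arms attenuating the loss.
#'
#' @param arms Character vector of treatment arm labels (subset of the four
#'   defaults, or custom labels if `arm_condition_effects` is supplied).
#' @param conditions Subset of `c("F", "F-T", "D2", "D6")`.
#' @param punches_per_condition Punches (= ovarian fragments) per arm and
#'   condition; the design default of 6 gives 24 punches per arm.
#' @param density_sections_per_punch,proliferation_sections_per_punch
#'   Sections cut from each punch for density/morphology assessment and for
#'   Ki-67 proliferation assessment.
#' @param baseline_log_density Baseline of the mean log10(count/mm^2 + 1).
#' @param arm_condition_effects Numeric `arms x conditions` matrix of
#'   log10-scale shifts added to the baseline.
#' @param fragment_sd,residual_sd Standard deviations of the per-fragment
#'   random effect and the per-section residual (log10 units).
#' @param p_degenerated,p_proliferative Per-condition probabilities that a
#'   primordial follicle is degenerated, or carries at least one
#'   Ki-67-positive granulosa cell; named by condition or recycled.
#' @param section_area_range Uniform range of section areas in mm^2.
#' @param seed Integer seed for reproducibility.
#' @return A `study_gen_config` list.
#' @export
study_gen_config <- function(arms = ARM_LEVELS,
                             conditions = CONDITION_LEVELS,
                             punches_per_condition = 6,
                             density_sections_per_punch = 12,
                             proliferation_sections_per_punch = 3,
                             baseline_log_density = 0,
                             arm_condition_effects = NULL,
                             fragment_sd = 0.2, residual_sd = 0.1,
                             p_degenerated = c(F = 0.25, `F-T` = 0.35,
                                               D2 = 0.5, D6 = 0.7),
                             p_proliferative = c(F = 0.05, `F-T` = 0.05,
                                                 D2 = 0.4, D6 = 0.2),
                             section_area_range = c(1.5, 2.5),
                             seed = NULL) {
  if (is.null(arm_condition_effects)) {
    if (!all(arms %in% ARM_LEVELS))
      stop_config("custom arm labels require an explicit arm_condition_effects matrix")
    if (!all(conditions %in% CONDITION_LEVELS))
      stop_config("conditions must be a subset of {F, F-T, D2, D6}")
    arm_condition_effects <- default_effects()[arms, conditions, drop = FALSE]
  }
  expand_p <- function(p, what) {
    if (is.null(names(p))) p <- stats::setNames(rep_len(p, length(conditions)), conditions)
    if (!all(conditions %in% names(p)))
      stop_config("%s must be named by condition", what)
    p <- p[conditions]
    if (any(p < 0 | p > 1)) stop_config("%s must lie in [0, 1]", what)
    p
  }
  cfg <- list(arms = arms, conditions = conditions,
              punches_per_condition = punches_per_condition,
              density_sections_per_punch = density_sections_per_punch,
              proliferation_sections_per_punch = proliferation_sections_per_punch,
              baseline_log_density = baseline_log_density,
              arm_condition_effects = arm_condition_effects,
              fragment_sd = fragment_sd, residual_sd = residual_sd,
              p_degenerated = expand_p(p_degenerated, "p_degenerated"),
              p_proliferative = expand_p(p_proliferative, "p_proliferative"),
              section_area_range = section_area_range, seed = seed)
  validate_study_gen_config(cfg)
  structure(cfg, class = "study_gen_config")
}

validate_study_gen_config <- function(cfg) {
  if (length(cfg$arms) < 1 || anyDuplicated(cfg$arms))
    stop_config("arms must be distinct labels")
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions))
    stop_config("conditions must be distinct labels")
  if (!is_count(cfg$punches_per_condition, 1))
    stop_config("punches_per_condition must be a count >= 1")
  if (!is_count(cfg$density_sections_per_punch, 1) ||
      !is_count(cfg$proliferation_sections_per_punch, 0))
    stop_config("section counts must be nonnegative counts (>= 1 density sections)")
  if (!is_number(cfg$fragment_sd) || cfg$fragment_sd < 0 ||
      !is_number(cfg$residual_sd) || cfg$residual_sd < 0)
    stop_config("fragment_sd and residual_sd must be >= 0")
  eff <- cfg$arm_condition_effects
  if (!is.matrix(eff) || nrow(eff) != length(cfg$arms) ||
      ncol(eff) != length(cfg$conditions) || anyNA(eff))
    stop_config("arm_condition_effects must be a complete arms x conditions matrix")
  if (length(cfg$section_area_range) != 2L || any(cfg$section_area_range <= 0))
    stop_config("section_area_range must be two positive areas (mm^2)")
  invisible(cfg)
}

# Back-transform a log10(X+1) value to a nonnegative integer follicle count
# for a section of the given area: X is a density per mm^2, the count is
# rounded to the nearest integer and floored at zero.
log_density_to_count <- function(y, area_mm2) {
  y <- pmax(y, 0)
  pmax(0L, as.integer(round((10^y - 1) * area_mm2)))
}

#' Simulate a follicle-annotation dataset
#'
#' Draws the full study table: one row per annotated follicle (plus one
#' placeholder row with `follicle_id = NA` for sections containing no
#' follicle, so section areas are preserved). Density/morphology sections
#' carry the three degeneration flags; proliferation sections carry the
#' Ki-67-positive granulosa count; the respective other fields are `NA`.
#' Follicle counts per section realize
#' `log10(count/mm^2 + 1) = baseline + effect[arm, condition] +
#' fragment_effect + residual` (truncated at zero before back-transform).
#' A small number of primary/secondary follicles is added per section;
#' they are recorded but excluded from every density outcome.
#'
#' @param cfg A [study_gen_config()].
#' @return A data.frame with columns `fragment_id`, `arm`, `condition`,
#'   `section_id`, `analysis_role` (`"density"` or `"proliferation"`),
#'   `section_area_mm2`, `follicle_id`, `stage`, `granulosa_disorganized`,
#'   `ooplasm_shrunken`, `oocyte_pyknotic`, `ki67_pos_granulosa_count`.
#' @export
generate_follicle_dataset <- function(cfg) {
  if (!inherits(cfg, "study_gen_config")) cfg <- do.call(study_gen_config, cfg)
  validate_study_gen_config(cfg)
  with_seed_if(cfg$seed, {
    frames <- expand.grid(punch = seq_len(cfg$punches_per_condition),
                          condition = cfg$conditions, arm = cfg$arms,
                          stringsAsFactors = FALSE)
    n_frag <- nrow(frames)
    frames$fragment_id <- sprintf("%s_%s_p%02d", frames$arm, frames$condition,
                                  frames$punch)
    frag_eff <- stats::rnorm(n_frag, 0, cfg$fragment_sd)
    mu <- cfg$baseline_log_density +
      cfg$arm_condition_effects[cbind(match(frames$arm, cfg$arms),
                                      match(frames$condition, cfg$conditions))]

    n_dens <- cfg$density_sections_per_punch
    n_prol <- cfg$proliferation_sections_per_punch
    n_sec <- n_dens + n_prol
    sec <- frames[rep(seq_len(n_frag), each = n_sec), , drop = FALSE]
    sec$section_index <- rep(seq_len(n_sec), n_frag)
    sec$analysis_role <- rep(c(rep("density", n_dens),
                               rep("proliferation", n_prol)), n_frag)
    sec$section_id <- paste0(sec$fragment_id, "_s", sprintf("%02d", sec$section_index))
    sec$section_area_mm2 <- stats::runif(nrow(sec), cfg$section_area_range[1],
                                         cfg$section_area_range[2])
    y <- rep(mu + frag_eff, each = n_sec) +
      stats::rnorm(nrow(sec), 0, cfg$residual_sd)
    sec$n_primordial <- log_density_to_count(y, sec$section_area_mm2)
    # occasional primary/secondary follicles, too scarce for analysis
    sec$n_mature <- stats::rpois(nrow(sec), 0.2)

    n_fol <- sec$n_primordial + sec$n_mature
    rows <- rep(seq_len(nrow(sec)), pmax(n_fol, 1L))
    df <- sec[rows, c("fragment_id", "arm", "condition", "section_id",
                      "analysis_role", "section_area_mm2"), drop = FALSE]
    # follicle index within section; 0 marks the placeholder of empty sections
    idx <- sequence(pmax(n_fol, 1L))
    empty <- rep(n_fol == 0L, pmax(n_fol, 1L))
    is_mature <- idx > rep(sec$n_primordial, pmax(n_fol, 1L)) & !empty
    n_rows <- nrow(df)

    df$follicle_id <- ifelse(empty, NA_character_,
                             paste0(df$section_id, "_f", sprintf("%03d", idx)))
    stage <- rep(NA_character_, n_rows)
    n_pm <- sum(!empty & !is_mature)
    stage[!empty & !is_mature] <- sample(c("primordial", "transitional"), n_pm,
                                         replace = TRUE, prob = c(0.85, 0.15))
    stage[is_mature] <- sample(c("primary", "secondary"), sum(is_mature),
                               replace = TRUE, prob = c(0.8, 0.2))
    df$stage <- stage

    cond_idx <- match(df$condition, cfg$conditions)
    is_density <- df$analysis_role == "density" & !empty
    is_prolif <- df$analysis_role == "proliferation" & !empty

    deg <- rep(NA, n_rows)
    deg[is_density] <- stats::runif(sum(is_density)) <
      cfg$p_degenerated[cond_idx[is_density]]
    flags <- matrix(NA, n_rows, 3)
    nd <- which(!is.na(deg) & deg)
    if (length(nd)) {
      # a degenerated follicle shows at least one of the three criteria
      f <- matrix(stats::runif(3 * length(nd)) < 0.5, ncol = 3)
      none <- !rowSums(f)
      f[cbind(which(none), sample.int(3, sum(none), replace = TRUE))] <- TRUE
      flags[nd, ] <- f
    }
    flags[!is.na(deg) & !deg, ] <- FALSE
    df$granulosa_disorganized <- flags[, 1]
    df$ooplasm_shrunken <- flags[, 2]
    df$oocyte_pyknotic <- flags[, 3]

    ki <- rep(NA_integer_, n_rows)
    if (any(is_prolif)) {
      pos <- stats::runif(sum(is_prolif)) < cfg$p_proliferative[cond_idx[is_prolif]]
      ki[is_prolif] <- ifelse(pos, 1L + stats::rpois(sum(is_prolif), 1), 0L)
    }
    df$ki67_pos_granulosa_count <- ki

    rownames(df) <- NULL
    df
  })
}

#' Write / read a follicle-annotation dataset as CSV
#'
#' @param annotations Data.frame as produced by [generate_follicle_dataset()].
#' @param path CSV file path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("fragment_id", "arm", "condition", "section_id", "analysis_role",
              "section_area_mm2", "follicle_id", "stage",
              "granulosa_disorganized", "ooplasm_shrunken", "oocyte_pyknotic",
              "ki67_pos_granulosa_count")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop_data("annotation table lacks columns: %s", paste(miss, collapse = ", "))
  for (f in c("granulosa_disorganized", "ooplasm_shrunken", "oocyte_pyknotic"))
    df[[f]] <- as.logical(df[[f]])
  df
}
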