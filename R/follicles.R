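#' Follicle scoring rules
#'
#' The density analysis is carried out on primordial follicles only;
#' transitional follicles (between the primordial and primary stages) are
#' counted as primordial, while the scarce primary and secondary follicles
#' are recorded but excluded. A follicle is *degenerated* when it shows any
#' of three morphological criteria — disorganized granulosa cells, shrunken
#' ooplasm, or a pyknotic oocyte — and *proliferative* when at least one
#' granulosa cell is Ki-67 positive.
#'
#' All three rules are vectorized over annotation-table columns.
#'
#' @param stage Character vector of follicle stages, from
#'   `c("primordial", "transitional", "primary", "secondary")`.
#' @name follicle-rules
NULL

#' @rdname follicle-rules
#' @return `is_primordial_for_analysis()`: logical, `TRUE` for primordial
#'   and transitional stages.
#' @export
is_primordial_for_analysis <- function(stage) {
  known <- stage %in% STAGE_LEVELS | is.na(stage)
  if (!all(known))
    stop_data("unknown follicle stage(s): %s",
              paste(unique(stage[!known]), collapse = ", "))
  !is.na(stage) & stage %in% c("primordial", "transitional")
}

#' @rdname follicle-rules
#' @param granulosa_disorganized,ooplasm_shrunken,oocyte_pyknotic Logical
#'   degeneration flags.
#' @return `classify_morphology()`: `"degenerated"` if any flag is set,
#'   otherwise `"normal"`.
#' @export
classify_morphology <- function(granulosa_disorganized, ooplasm_shrunken,
                                oocyte_pyknotic) {
  deg <- granulosa_disorganized | ooplasm_shrunken | oocyte_pyknotic
  ifelse(deg, "degenerated", "normal")
}

#' @rdname follicle-rules
#' @param ki67_pos_granulosa_count Nonnegative integer count of
#'   Ki-67-positive granulosa cells.
#' @return `is_proliferative()`: logical, `TRUE` when the count is >= 1.
#' @export
is_proliferative <- function(ki67_pos_granulosa_count) {
  if (any(ki67_pos_granulosa_count < 0, na.rm = TRUE))
    stop_data("ki67_pos_granulosa_count must be >= 0")
  !is.na(ki67_pos_granulosa_count) & ki67_pos_granulosa_count >= 1
}

#' Log10(X + 1) outcome transform
#'
#' The study's outcome scale for follicle densities: `log10(x + 1)`,
#' which maps a zero count to zero and compresses the right tail.
#'
#' @param x Nonnegative numeric vector (densities per mm^2).
#' @export
log10p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop_data("raw densities must be >= 0")
  log10(x + 1)
}

OUTCOME_LEVELS <- c("total_primordial", "normal_primordial",
                    "proliferative_primordial", "global_proliferation")

# Which sections and follicles qualify for an annotation-based outcome.
outcome_role <- function(outcome) {
  switch(outcome,
         total_primordial = ,
         normal_primordial = "density",
         proliferative_primordial = "proliferation",
         stop_config("unknown annotation outcome '%s'", outcome))
}

qualifies <- function(df, outcome) {
  p <- is_primordial_for_analysis(df$stage)
  switch(outcome,
         total_primordial = p,
         normal_primordial = p & !is.na(df$granulosa_disorganized) &
           classify_morphology(df$granulosa_disorganized, df$ooplasm_shrunken,
                               df$oocyte_pyknotic) == "normal",
         proliferative_primordial = p &
           is_proliferative(df$ki67_pos_granulosa_count))
}

#' Per-fragment follicle density on the log10(X+1) scale
#'
#' Pools all qualifying sections of one fragment: the raw density is the
#' total qualifying follicle count divided by the total area of those
#' sections (counts and areas are pooled, not averaged per section, so
#' unequal section areas are weighted correctly), and the reported value
#' is `log10(raw + 1)`.
#'
#' @param frag Data.frame of one fragment's annotation rows (the schema of
#'   [generate_follicle_dataset()]).
#' @param outcome One of `"total_primordial"`, `"normal_primordial"`,
#'   `"proliferative_primordial"`.
#' @return One-row data.frame: `fragment_id`, `arm`, `condition`, `outcome`,
#'   `raw_per_mm2`, `log_value`.
#' @export
fragment_density <- function(frag, outcome = "total_primordial") {
  role <- outcome_role(outcome)
  if (length(unique(frag$fragment_id)) != 1L)
    stop_data("fragment_density expects rows of exactly one fragment")
  sub <- frag[frag$analysis_role == role, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_data("no sections for outcome '%s' (role '%s') on fragment %s",
              outcome, role, frag$fragment_id[1])
  if (any(sub$section_area_mm2 <= 0))
    stop_data("section areas must be positive")
  sec_area <- tapply(sub$section_area_mm2, sub$section_id, function(a) a[1])
  total_area <- sum(sec_area)
  n <- sum(qualifies(sub, outcome), na.rm = TRUE)
  raw <- n / total_area
  data.frame(fragment_id = frag$fragment_id[1], arm = frag$arm[1],
             condition = frag$condition[1], outcome = outcome,
             raw_per_mm2 = raw, log_value = log10p1(raw),
             stringsAsFactors = FALSE)
}

#' Score a whole study into density observations
#'
#' Vectorized scoring of an annotation table into the tidy observation
#' table the mixed model consumes. At `level = "section"` each section
#' contributes one observation (the modeling unit: the fragment random
#' intercept is then identified from within-fragment replication); at
#' `level = "fragment"` counts and areas are pooled across each fragment's
#' qualifying sections, one observation per fragment (the reporting unit).
#'
#' @param annotations Annotation data.frame
#'   (schema of [generate_follicle_dataset()]).
#' @param outcomes Subset of `c("total_primordial", "normal_primordial",
#'   "proliferative_primordial")`.
#' @param level `"section"` or `"fragment"`.
#' @return Data.frame with `fragment_id`, `arm`, `condition`, `section_id`
#'   (section level only), `outcome`, `raw_per_mm2`, `log_value`.
#' @export
score_study <- function(annotations,
                        outcomes = c("total_primordial", "normal_primordial",
                                     "proliferative_primordial"),
                        level = c("fragment", "section")) {
  level <- match.arg(level)
  out <- lapply(outcomes, function(oc) {
    role <- outcome_role(oc)
    sub <- annotations[annotations$analysis_role == role, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (any(sub$section_area_mm2 <= 0)) stop_data("section areas must be positive")
    q <- qualifies(sub, oc)
    q[is.na(q)] <- FALSE
    key <- if (level == "section") sub$section_id else sub$fragment_id
    counts <- rowsum(as.numeric(q), key)
    # one area per section, then summed within the grouping key
    first <- !duplicated(sub$section_id)
    areas <- rowsum(sub$section_area_mm2[first],
                    (if (level == "section") sub$section_id else sub$fragment_id)[first])
    stopifnot(identical(rownames(counts), rownames(areas)))
    meta <- sub[!duplicated(key), c("fragment_id", "arm", "condition",
                                    "section_id")]
    meta <- meta[match(rownames(counts), if (level == "section")
      meta$section_id else meta$fragment_id), ]
    raw <- counts[, 1] / areas[, 1]
    res <- data.frame(fragment_id = meta$fragment_id, arm = meta$arm,
                      condition = meta$condition, outcome = oc,
                      raw_per_mm2 = as.numeric(raw),
                      log_value = log10p1(as.numeric(raw)),
                      stringsAsFactors = FALSE)
    if (level == "section") res$section_id <- meta$section_id
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
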