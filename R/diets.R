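# Hypothetical protein diets and their pairwise comparisons.
#
# A diet is an 11-day sequence of intake levels (I/II/III). The two "late"
# diets are anchored on the base they add protein to (late standard adds
# level II to an exclusively low diet on days #5-#11; late high adds level
# III to a standard diet). The early high diet specifies level III on days
# #1-#4 only; its remaining days are copied from the comparison diet, so it
# is resolved per comparison.

DIET_NAMES <- c("exclusively_low", "late_standard", "early_standard",
                "late_high", "early_high")

#' The five hypothetical protein diets
#'
#' Returns the five hypothetical 11-day protein diets used for
#' ceteris-paribus hazard contrasts: an exclusively low diet (level I on all
#' days), a late standard diet (low on days #1--#4, standard on #5--#11),
#' an early standard diet (standard on all days), a late high diet
#' (standard on #1--#4, high on #5--#11) and an early high diet (high on
#' days #1--#4; unspecified days are copied from the comparison diet when a
#' pair is resolved, encoded as `NA`).
#'
#' @return Named list of `protein_diet` objects; each has `name`, `levels`
#'   (character vector of length 11, possibly `NA` for context-dependent
#'   days) and `gkg` (the within-level median intake in g/kg as a numeric
#'   illustration; the model consumes levels only).
#' @export
#' @examples
#' names(make_diets())
make_diets <- function() {
  lev <- function(x) factor(x, levels = c("I", "II", "III"))
  def <- list(
    exclusively_low = rep("I", 11),
    late_standard   = c(rep("I", 4), rep("II", 7)),
    early_standard  = rep("II", 11),
    late_high       = c(rep("II", 4), rep("III", 7)),
    early_high      = c(rep("III", 4), rep(NA, 7))
  )
  out <- lapply(names(def), function(nm) {
    levels_chr <- def[[nm]]
    structure(list(
      name = nm,
      levels = levels_chr,
      gkg = unname(LEVEL_MEDIANS[levels_chr])
    ), class = "protein_diet")
  })
  names(out) <- names(def)
  out
}

#' @export
print.protein_diet <- function(x, ...) {
  cat("<protein_diet>", x$name, "\n")
  cat("  days #1-#11:", paste(ifelse(is.na(x$levels), ".", x$levels),
                              collapse = " "), "\n")
  invisible(x)
}

resolve_pair <- function(ref, alt) {
  rl <- ref$levels; al <- alt$levels
  if (any(is.na(rl) & is.na(al))) {
    stop("diet pair leaves a day unspecified in both diets", call. = FALSE)
  }
  rl[is.na(rl)] <- al[is.na(rl)]
  al[is.na(al)] <- rl[is.na(al)]
  list(ref = rl, alt = al)
}

#' The six pairwise diet comparisons
#'
#' Builds the six ordered diet pairs whose time-varying cause-specific
#' hazard ratios the analysis reports. The reference diet of each pair is
#' the one providing less protein; unspecified days of a diet are resolved
#' by copying the comparison diet's level for that day, so every resolved
#' pair is nested (component-wise `ref <= alt`).
#'
#' @return List of six comparisons; each element has `name`,
#'   `ref_name`, `alt_name`, and resolved level vectors `ref` and `alt`
#'   (character, length 11, no `NA`).
#' @export
#' @examples
#' length(make_comparisons())
make_comparisons <- function() {
  d <- make_diets()
  pairs <- list(
    c("exclusively_low", "late_standard"),
    c("late_standard", "early_standard"),
    c("exclusively_low", "early_standard"),
    c("early_standard", "late_high"),
    c("late_high", "early_high"),
    c("early_standard", "early_high")
  )
  out <- lapply(pairs, function(p) {
    res <- resolve_pair(d[[p[1]]], d[[p[2]]])
    ord <- c(I = 1L, II = 2L, III = 3L)
    if (any(ord[res$ref] > ord[res$alt])) {
      stop("reference diet must provide component-wise less protein", call. = FALSE)
    }
    list(
      name = paste(p[1], "vs", p[2]),
      ref_name = p[1], alt_name = p[2],
      ref = res$ref, alt = res$alt
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
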