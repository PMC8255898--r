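#' Compare traits between two groups
#'
#' Per trait: mean and standard deviation per group and a two-sided t-test.
#' Welch's unequal-variance t is the default (group variances in carcass /
#' meat-quality tables commonly differ several-fold); set `pooled = TRUE`
#' for the classical pooled-variance Student's t. Traits with fewer than 2
#' observations in either group are skipped with a warning.
#'
#' @param table Data frame with one row per animal, a group column and
#'   numeric trait columns.
#' @param traits Character vector of trait column names.
#' @param group_col Name of the group column (must have exactly 2 levels).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return Data frame `trait, mean_1, sd_1, n_1, mean_2, sd_2, n_2,
#'   t_statistic, p_value` (groups in level order).
#' @export
compare_traits <- function(table, traits, group_col = "group",
                           pooled = FALSE) {
  if (!group_col %in% names(table)) fail("no column '%s'", group_col)
  g <- as.factor(table[[group_col]])
  if (nlevels(g) != 2L) fail("exactly two groups are required")
  lv <- levels(g)
  rows <- lapply(traits, function(tr) {
    if (!tr %in% names(table)) fail("no trait column '%s'", tr)
    x <- table[[tr]][g == lv[1]]; y <- table[[tr]][g == lv[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    row <- data.frame(trait = tr,
                      mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
                      mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
                      t_statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("trait '%s' skipped: fewer than 2 observations in a group",
                      tr), call. = FALSE)
      return(row)
    }
    tt <- tryCatch(t.test(x, y, var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # zero variance in both groups: t is 0 when the means agree
      if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
        row$t_statistic <- 0; row$p_value <- 1
      } else {
        warning(sprintf("trait '%s': t-test undefined (constant data)", tr),
                call. = FALSE)
      }
      return(row)
    }
    row$t_statistic <- unname(tt$statistic)
    row$p_value <- tt$p.value
    row
  })
  do.call(rbind, rows)
}

#' Default fatty-acid class map
#'
#' SFA, MUFA and PUFA membership by fatty-acid shorthand; fully overridable
#' in [fatty_acid_classes()].
#' @return Named list of character vectors.
#' @export
default_fa_classes <- function() {
  list(SFA = c("C14:0", "C16:0", "C18:0", "C20:0"),
       MUFA = c("C16:1", "C18:1", "C20:1"),
       PUFA = c("C18:2", "C18:3", "C20:4", "C20:5", "C22:6"))
}

#' Fatty-acid class totals per animal (and per group)
#'
#' Sums the individual fatty-acid columns into saturated (SFA),
#' monounsaturated (MUFA) and polyunsaturated (PUFA) class totals plus a
#' grand total (SFA + MUFA + PUFA); additivity is exact. Fatty-acid columns
#' are those matching the `Cxx:y` shorthand; any such column not covered by
#' the class map is an error.
#'
#' @param table Data frame with per-animal rows and fatty-acid columns named
#'   by shorthand (e.g. `C18:1`). Other columns pass through.
#' @param class_map Named list assigning each fatty-acid column to exactly
#'   one class (default [default_fa_classes()]).
#' @return The input with `SFA`, `MUFA`, `PUFA` and `total_fa` columns
#'   appended (empty classes contribute 0).
#' @export
fatty_acid_classes <- function(table, class_map = default_fa_classes()) {
  fa_cols <- grep("^C[0-9]+:[0-9]+$", names(table), value = TRUE)
  mapped <- unlist(class_map, use.names = FALSE)
  unmapped <- setdiff(fa_cols, mapped)
  if (length(unmapped))
    fail("fatty-acid column(s) not in the class map: %s",
         paste(unmapped, collapse = ", "))
  dup <- mapped[duplicated(mapped)]
  if (length(dup))
    fail("fatty acid(s) assigned to more than one class: %s",
         paste(unique(dup), collapse = ", "))
  class_total <- function(members) {
    cols <- intersect(members, fa_cols)
    if (length(cols) == 0) return(rep(0, nrow(table)))
    rowSums(table[, cols, drop = FALSE])
  }
  out <- table
  for (cl in c("SFA", "MUFA", "PUFA"))
    out[[cl]] <- class_total(class_map[[cl]])
  out$total_fa <- out$SFA + out$MUFA + out$PUFA
  out
}
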