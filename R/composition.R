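#' Read a (class, family, count) abundance table
#'
#' TSV with columns `class`, `family`, `count` — e.g. a transposable-
#' element annotation summary with classes "Class I", "Class II" and
#' "Ambiguous". (class, family) pairs must be unique, counts
#' non-negative.
#'
#' @param path TSV file.
#' @return data.frame with `class`, `family`, `count`.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "family", "count") %in% names(df)))
  if (any(df$count < 0)) stop("counts must be non-negative")
  if (anyDuplicated(df[, c("class", "family")]))
    stop("(class, family) pairs must be unique")
  df
}

#' Composition summary of an abundance table
#'
#' For every row computes its percentage share of the grand total and of
#' its class total, rounded half-up to 2 decimals (the printed precision
#' of published composition tables). Rows of class `"Ambiguous"` belong
#' to no class: they count toward the grand total but get no
#' within-class share.
#'
#' @param table abundance data.frame (`class`, `family`, `count`).
#' @return object of class `composition_summary`: the input with
#'   `frequency_in_total` and `frequency_in_class` columns, plus
#'   attributes `class_totals` and `grand_total`.
#' @export
composition_table <- function(table) {
  if (!nrow(table)) stop("empty abundance table")
  grand <- sum(table$count)
  if (grand <= 0) stop("grand total must be positive")
  is_classed <- table$class != "Ambiguous"
  class_totals <- tapply(table$count[is_classed], table$class[is_classed], sum)
  out <- table
  out$frequency_in_total <- round_half_up(100 * table$count / grand, 2)
  out$frequency_in_class <- ifelse(
    is_classed,
    round_half_up(100 * table$count /
                    as.numeric(class_totals[table$class]), 2),
    NA_real_)
  structure(out, class_totals = class_totals, grand_total = grand,
            class = c("composition_summary", "data.frame"))
}

#' Percentage share of one class
#'
#' @param table abundance data.frame.
#' @param class_label the class (e.g. `"Class I"`).
#' @return `100 * class_total / grand_total`, rounded half-up to 1
#'   decimal.
#' @export
class_share <- function(table, class_label) {
  if (!class_label %in% table$class) stop("unknown class: ", class_label)
  round_half_up(100 * sum(table$count[table$class == class_label]) /
                  sum(table$count), 1)
}

#' Percentage share of a family group
#'
#' Sums the named families and expresses them as a share of the grand
#' total or of their class total (families must then share one class).
#'
#' @param table abundance data.frame.
#' @param families character vector of family labels.
#' @param denominator `"total"` (grand total) or `"class"` (the families'
#'   class total).
#' @return percentage rounded half-up to 1 decimal.
#' @export
family_group_share <- function(table, families,
                               denominator = c("total", "class")) {
  denominator <- match.arg(denominator)
  missing <- setdiff(families, table$family)
  if (length(missing))
    stop("unknown family(ies): ", paste(missing, collapse = ", "))
  rows <- table[table$family %in% families, ]
  den <- if (denominator == "total") sum(table$count) else {
    cls <- unique(rows$class)
    if (length(cls) != 1)
      stop("families span multiple classes; use denominator = 'total'")
    sum(table$count[table$class == cls])
  }
  round_half_up(100 * sum(rows$count) / den, 1)
}

#' Coverage percentage
#'
#' The share of a reference catalogue recovered in an assembly, e.g.
#' transcription-factor homologs identified out of those annotated.
#'
#' @param identified number identified (0 <= identified <= total).
#' @param total catalogue size (> 0).
#' @return object of class `coverage_stat`: list with `identified`,
#'   `total` and `percent` (half-up, 1 decimal).
#' @export
coverage_percent <- function(identified, total) {
  stopifnot(total > 0, identified >= 0)
  if (identified > total) stop("identified cannot exceed total")
  structure(list(identified = identified, total = total,
                 percent = round_half_up(100 * identified / total, 1)),
            class = "coverage_stat")
}

#' @export
print.coverage_stat <- function(x, ...) {
  cat(sprintf("%d / %d identified (%.1f%%)\n", x$identified, x$total,
              x$percent))
  invisible(x)
}

#' Write a composition summary as TSV
#'
#' @param x a [composition_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
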