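#' Aggregate mapped-read counts into an expression profile
#'
#' Venom-gland transcriptome profiling: per-contig mapped-read counts are
#' aggregated into relative expression percentages at two levels — a top
#' level over the groups toxin / non_toxin / unidentified, and a
#' within-toxin level over toxin families. Raw read-count proportions are
#' used without transcript-length (RPKM) normalization: the abundant toxin
#' transcripts of venom glands are short, and length correction is not
#' applied in this analysis by design.
#'
#' @param counts Tibble/data.frame with columns `contig` (unique ids),
#'   `group` (`"toxin"`, `"non_toxin"` or `"unidentified"`), `family`
#'   (family name within the group; may be `NA` for unidentified) and
#'   `count` (non-negative integer mapped reads).
#' @return List with two tibbles: `top` (`group`, `reads`, `pct`) and
#'   `toxin_families` (`family`, `reads`, `pct`, percentages of the toxin
#'   reads only). Percentages sum to 100 at each level and are reported at
#'   full precision; round to 1 decimal for display.
#' @examples
#' toy <- tibble::tibble(
#'   contig = c("c1", "c2", "c3"),
#'   group = c("toxin", "non_toxin", "unidentified"),
#'   family = c("pilosulin-like", NA, NA),
#'   count = c(451, 452, 97)
#' )
#' expression_profile(toy)$top
#' @export
expression_profile <- function(counts) {
  required <- c("contig", "group", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("count table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"family" %in% names(counts)) counts$family <- NA_character_
  if (anyDuplicated(counts$contig)) {
    stop("contig ids must be unique", call. = FALSE)
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  groups <- c("toxin", "non_toxin", "unidentified")
  bad <- setdiff(unique(counts$group), groups)
  if (length(bad) > 0) {
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(groups, collapse = "/"), call. = FALSE)
  }
  total <- sum(counts$count)
  if (total == 0) stop("total read count is zero", call. = FALSE)

  top_reads <- vapply(
    groups,
    function(g) sum(counts$count[counts$group == g]),
    numeric(1), USE.NAMES = FALSE
  )
  top <- tibble::tibble(
    group = groups,
    reads = as.numeric(top_reads),
    pct = 100 * top_reads / total
  )

  tox <- counts[counts$group == "toxin", , drop = FALSE]
  if (nrow(tox) > 0 && sum(tox$count) > 0) {
    fam_reads <- tapply(tox$count, tox$family, sum)
    toxin_families <- tibble::tibble(
      family = names(fam_reads),
      reads = as.numeric(fam_reads),
      pct = 100 * as.numeric(fam_reads) / sum(tox$count)
    )
    toxin_families <-
      toxin_families[order(-toxin_families$reads, toxin_families$family), ]
  } else {
    toxin_families <- tibble::tibble(
      family = character(), reads = numeric(), pct = numeric()
    )
  }

  list(top = top, toxin_families = toxin_families)
}

#' Pie chart of an expression profile
#'
#' @param profile Output of [expression_profile()].
#' @param level `"top"` or `"toxin_families"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_expression_profile <- function(profile, level = c("top",
                                                       "toxin_families")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_expression_profile() requires ggplot2", call. = FALSE)
  }
  level <- match.arg(level)
  df <- profile[[level]]
  df$slice <- if (level == "top") df$group else df$family
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$pct,
                                   fill = .data$slice)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL,
                  title = "Relative expression (% of mapped reads)") +
    ggplot2::theme_void()
}
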