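#' System Usability Scale score for one respondent
#'
#' Standard SUS scoring: ten 5-point Likert items of alternating polarity;
#' odd items contribute `item - 1`, even items `5 - item`, and the summed
#' contributions are scaled by 2.5 onto 0-100.
#'
#' @param items Integer vector of exactly 10 responses, each in 1..5
#'   (1 = strongly disagree, 5 = strongly agree).
#' @return Score in \[0, 100\].
#' @examples
#' sus_score(rep(3, 10))  # 50
#' @export
sus_score <- function(items) {
  if (length(items) != 10L)
    stop("a SUS response has exactly 10 items", call. = FALSE)
  if (anyNA(items) || any(items < 1 | items > 5 | items != as.integer(items)))
    stop("SUS items must be integers in 1..5", call. = FALSE)
  odd <- items[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - items[c(2, 4, 6, 8, 10)]
  2.5 * sum(odd, even)
}

#' Aggregate SUS responses across raters
#'
#' Scores each response, averages, and labels the mean score:
#' below 50 `unacceptable`, 50-70 `marginal` (inclusive at both ends),
#' above 70 `good`.
#'
#' @param responses A list of 10-item response vectors, or a data frame /
#'   matrix with one respondent per row and the 10 item columns (an id
#'   column named `rater_id` is allowed and ignored for scoring).
#' @return List of class `sus_summary`: `per_rater_scores`, `mean_score`,
#'   `label`, `n_raters`.
#' @examples
#' sus_aggregate(list(rep(5:1, 4)[1:10], rep(3, 10)))
#' @export
sus_aggregate <- function(responses) {
  if (is.data.frame(responses) || is.matrix(responses)) {
    df <- as.data.frame(responses)
    df$rater_id <- NULL
    responses <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, ]))
  }
  if (!length(responses)) stop("at least one response required", call. = FALSE)
  scores <- vapply(responses, sus_score, numeric(1))
  m <- mean(scores)
  label <- if (m < 50) "unacceptable" else if (m <= 70) "marginal" else "good"
  structure(list(per_rater_scores = scores, mean_score = m, label = label,
                 n_raters = length(scores)),
            class = "sus_summary")
}

#' @export
print.sus_summary <- function(x, ...) {
  cat(sprintf("SUS: mean %.1f over %d rater(s) -> %s\n",
              x$mean_score, x$n_raters, x$label))
  invisible(x)
}
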