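# FFMQ-SF scoring: 19 items, 4 subscales (observing, acting with awareness,
# nonjudging of inner experience, nonreactivity to inner experience), 5-point
# Likert responses, describing subscale not administered.  Totals range 19-95.

FFMQ_SUBSCALES <- c("observing", "acting_with_awareness", "nonjudging",
                    "nonreactivity")

#' Load an FFMQ-SF scoring key
#'
#' Reads a YAML key (item-to-subscale map, reverse-scored item set, scale
#' bounds) and validates its shape: 19 items in total, 4 for observing and
#' 5 for each remaining subscale, reverse set a subset of the items.  The
#' packaged default follows the published short-form assignment with the
#' describing subscale removed and the reverse-scored items concentrated in
#' acting-with-awareness and nonjudging; deployments that log a different
#' key can supply their own file.
#'
#' @param path YAML key file; `NULL` loads the packaged default.
#' @return list of class `ffmq_key` with `items`, `subscales` (named list
#'   of item-id vectors), `reverse`, `scale_min`, `scale_max`.
#' @export
ffmq_key <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ffmq_key.yaml", package = "mhengage")
  }
  raw <- yaml::read_yaml(path)
  subscales <- lapply(raw$subscales, as.character)
  items <- unlist(subscales, use.names = FALSE)
  reverse <- as.character(raw$reverse_scored %||% character(0))
  if (!setequal(names(subscales), FFMQ_SUBSCALES)) {
    stop("key must define exactly the four administered subscales")
  }
  if (anyDuplicated(items)) stop("items assigned to more than one subscale")
  if (length(items) != 19L) stop("key must contain 19 items in total")
  if (length(subscales$observing) != 4L ||
      !all(lengths(subscales[setdiff(FFMQ_SUBSCALES, "observing")]) == 5L)) {
    stop("observing must have 4 items and each remaining subscale 5")
  }
  if (!all(reverse %in% items)) stop("reverse-scored ids must be key items")
  structure(list(items = items, subscales = subscales, reverse = reverse,
                 scale_min = raw$scale_min %||% 1,
                 scale_max = raw$scale_max %||% 5),
            class = "ffmq_key")
}

#' @method print ffmq_key
#' @export
print.ffmq_key <- function(x, ...) {
  cat(sprintf("<ffmq_key> %d items, %d reverse-scored, scale %d-%d\n",
              length(x$items), length(x$reverse), x$scale_min, x$scale_max))
  invisible(x)
}

#' Score one FFMQ-SF assessment occasion
#'
#' Reverse-scored items are mapped `r -> 6 - r`, each subscale is the sum of
#' its items, and the total is the sum of the four subscales (bounds 19-95).
#'
#' @param responses named numeric vector, item id to raw response (1-5).
#' @param key an `ffmq_key`.
#' @param missing `"reject"` (default) refuses occasions with unanswered
#'   items; `"prorate"` imputes a subscale as its answered-item mean times
#'   its item count when at least 80\% of the subscale is answered.
#' @return named list: one score per subscale plus `total`.
#' @examples
#' key <- ffmq_key()
#' r <- setNames(rep(3, 19), key$items)
#' score_occasion(r, key)$total  # 57
#' @export
score_occasion <- function(responses, key = ffmq_key(),
                           missing = c("reject", "prorate")) {
  missing <- match.arg(missing)
  stopifnot(inherits(key, "ffmq_key"))
  unknown <- setdiff(names(responses), key$items)
  if (length(unknown)) {
    stop(sprintf("unknown item id(s): %s", paste(unknown, collapse = ", ")))
  }
  bad <- responses < key$scale_min | responses > key$scale_max |
    responses != round(responses)
  if (any(bad, na.rm = TRUE) || anyNA(responses)) {
    stop(sprintf("responses must be integers in [%d, %d]",
                 key$scale_min, key$scale_max))
  }
  flip <- key$scale_min + key$scale_max  # 6 on the standard 1-5 scale
  scored <- responses
  rv <- intersect(names(responses), key$reverse)
  scored[rv] <- flip - scored[rv]
  out <- lapply(key$subscales, function(ids) {
    x <- scored[intersect(ids, names(scored))]
    n_miss <- length(ids) - length(x)
    if (n_miss > 0L) {
      if (missing == "reject" || length(x) < 0.8 * length(ids)) {
        stop(sprintf("unanswered item(s) in subscale: %s",
                     paste(setdiff(ids, names(scored)), collapse = ", ")))
      }
      return(mean(x) * length(ids))
    }
    sum(x)
  })
  out$total <- sum(unlist(out))
  out
}

# Apply double reversal sanity: reversing twice is the identity (exported
# mainly for property tests / key audits).
#' Reverse-score responses under a key
#'
#' Maps every reverse-scored item `r -> 6 - r` (on the standard 1-5 scale).
#' Applying it twice returns the original responses.
#'
#' @param responses named response vector.
#' @param key an `ffmq_key`.
#' @return responses with reverse-scored items flipped.
#' @export
reverse_score <- function(responses, key = ffmq_key()) {
  rv <- intersect(names(responses), key$reverse)
  responses[rv] <- (key$scale_min + key$scale_max) - responses[rv]
  responses
}
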