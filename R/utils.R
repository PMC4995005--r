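# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raise a classed soilcmin error
#'
#' @param msg message
#' @param class subclass, e.g. "schema"
#' @param ... extra fields stored on the condition
#' @noRd
cmin_abort <- function(msg, class, ...) {
  stop(errorCondition(msg,
                      class = c(paste0("soilcmin_", class, "_error"),
                                "soilcmin_error"),
                      ...))
}

cmin_warn <- function(msg, class, ...) {
  warning(warningCondition(msg,
                           class = c(paste0("soilcmin_", class, "_warning"),
                                     "soilcmin_warning"),
                           ...))
}

#' Significance code for a p-value
#'
#' Maps a p-value to the conventional code used in the model report:
#' `***` (p < 0.001), `**` (p < 0.01), `*` (p < 0.05), `°`
#' (p < 0.1) and `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of codes.
#' @export
#' @examples
#' sig_code(c(1e-4, 0.03, 0.07, 0.2))
sig_code <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep("ns", length(p))
  out[p < 0.1]   <- "°"
  out[p < 0.05]  <- "*"
  out[p < 0.01]  <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Mean squared error of prediction from paired values
#'
#' The prediction-error summary used throughout the selection procedure:
#' the mean of squared differences between observations and predictions,
#' ignoring pairs where the prediction is missing (e.g. a failed
#' cross-validation fold).
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return a single number; attribute `n` holds the number of pairs used.
#' @export
#' @examples
#' msep_values(c(1, 2, 3), c(1, 1, 1)) # 5/3
msep_values <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ok <- !is.na(y) & !is.na(yhat)
  if (!any(ok)) cmin_abort("no complete observation/prediction pairs", "data")
  out <- mean((y[ok] - yhat[ok])^2)
  attr(out, "n") <- sum(ok)
  out
}

# Compact letter display from a logical "significantly different" matrix.
# Insert-and-absorb: start from one group holding every level, split on
# each significant pair, drop groups that are subsets of others.
compact_letters <- function(diff_mat, means) {
  lev <- rownames(diff_mat)
  groups <- list(lev)
  pairs <- which(diff_mat & upper.tri(diff_mat), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- lev[pairs[r, 1]]; b <- lev[pairs[r, 2]]
      new_groups <- list()
      for (g in groups) {
        if (all(c(a, b) %in% g)) {
          new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
        } else new_groups <- c(new_groups, list(g))
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_groups))
      for (i in seq_along(new_groups)) {
        for (j in seq_along(new_groups)) {
          if (i != j && keep[j] &&
              all(new_groups[[i]] %in% new_groups[[j]]) &&
              !(all(new_groups[[j]] %in% new_groups[[i]]) && i < j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      groups <- unique(new_groups[keep])
    }
  }
  # order groups by the mean of their best level so 'a' tags the largest
  ord <- order(-vapply(groups, function(g) max(means[g]), numeric(1)))
  groups <- groups[ord]
  letters_per_level <- vapply(lev, function(l) {
    paste0(letters[which(vapply(groups, function(g) l %in% g, logical(1)))],
           collapse = "")
  }, character(1))
  letters_per_level
}
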