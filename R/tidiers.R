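#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, k = NULL, ...) {
  k <- k %||% x$chosen_k
  tibble(sample_id = x$labels$sample_id,
         k = k,
         label = consensus_labels(x, k))
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  best <- x$metrics[x$metrics$k == x$chosen_k, ]
  tibble(chosen_k = x$chosen_k, pac = best$pac,
         reps = x$reps, subsample_frac = x$subsample_frac, inner = x$inner)
}

#' @method tidy nmf_result
#' @export
tidy.nmf_result <- function(x, rank = NULL, ...) {
  rank <- rank %||% x$chosen_rank
  fit <- x$fits[[as.character(rank)]]
  if (is.null(fit)) abort(paste0("rank ", rank, " was not fitted."))
  tibble(sample_id = names(fit$labels), rank = rank,
         label = unname(fit$labels))
}

#' @method glance nmf_result
#' @export
glance.nmf_result <- function(x, ...) {
  best <- x$metrics[x$metrics$rank == x$chosen_rank, ]
  tibble(chosen_rank = x$chosen_rank, cophenetic = best$cophenetic,
         divergence = best$best_divergence)
}

#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p = x$p)
}

#' @method tidy km_result
#' @export
tidy.km_result <- function(x, ...) {
  x$medians
}

#' @method tidy nri_result
#' @export
tidy.nri_result <- function(x, ...) {
  tibble(component = c("event", "nonevent", "total"),
         nri = c(x$nri_event, x$nri_nonevent, x$nri),
         horizon = x$horizon)
}
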