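# broom-style tidiers and ggplot2 methods for fitted objects.

#' Tidy a fitted model into a per-spot tibble
#'
#' @param x an `st_fit`.
#' @param embedding include the d embedding columns (`f1..fd`)?
#' @param ... unused.
#' @return tibble with `barcode`, `batch`, `x`, `y`, `domain` and optionally
#'   the embedding columns.
#' @method tidy st_fit
#' @export
tidy.st_fit <- function(x, embedding = FALSE, ...) {
  out <- as_tibble(x$spots[, c("barcode", "batch", "x", "y", "domain")])
  out$domain <- factor(out$domain)
  if (isTRUE(embedding)) {
    emb <- as_tibble(as.data.frame(x$embedding),
                     .name_repair = ~ paste0("f", seq_along(.x)))
    out <- dplyr::bind_cols(out, emb)
  }
  out
}

#' One-row model summary
#'
#' @param x an `st_fit`.
#' @param ... unused.
#' @return tibble with dimensions, iteration count, convergence flag, final
#'   objective and the fraction of loading entries with inclusion
#'   probability above 1/2.
#' @method glance st_fit
#' @export
glance.st_fit <- function(x, ...) {
  tibble(n = nrow(x$embedding), p = length(x$genes),
         d = x$hyper$d, q = x$hyper$q,
         n_iter = x$n_iter, converged = x$converged,
         objective = x$objective_trace[x$n_iter],
         prop_selected = mean(x$params$incl > 0.5))
}

#' Plot a fitted model
#'
#' `type = "domains"` draws the spatial domain map per slice;
#' `type = "objective"` draws the objective trace.
#'
#' @param object an `st_fit`.
#' @param type `"domains"` or `"objective"`.
#' @param point_size spot size for the domain map.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot st_fit
#' @export
autoplot.st_fit <- function(object, type = c("domains", "objective"),
                            point_size = 0.8, ...) {
  type <- match.arg(type)
  if (type == "objective") {
    df <- tibble(iteration = seq_len(object$n_iter),
                 objective = object$objective_trace)
    return(ggplot(df, aes(x = .data$iteration, y = .data$objective)) +
             geom_line() +
             labs(x = "EM iteration", y = "marginal log joint") +
             theme_minimal())
  }
  df <- tidy.st_fit(object)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$domain)) +
    geom_point(size = point_size) +
    coord_equal() +
    facet_wrap(~batch) +
    labs(x = NULL, y = NULL, colour = "domain") +
    theme_minimal()
}

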