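# Result containers and their broom/ggplot2 methods.

new_hyperbolic_embedding <- function(method, coords, params, extras = list()) {
  stopifnot(is.data.frame(coords),
            all(c("node", "r", "theta") %in% names(coords)))
  coords$theta <- normalize_angle(coords$theta)
  obj <- c(list(method = method, coords = coords, params = params), extras)
  class(obj) <- "hyperbolic_embedding"
  obj
}

#' @export
print.hyperbolic_embedding <- function(x, ...) {
  cat(sprintf("Hyperbolic embedding (%s): %d nodes\n", x$method, nrow(x$coords)))
  p <- x$params[!vapply(x$params, is.null, logical(1))]
  if (length(p) > 0) {
    cat("  ", paste(sprintf("%s = %s", names(p),
                            vapply(p, function(v) format(v, digits = 4),
                                   character(1))),
                    collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood: %.4g\n", x$loglik))
  print(utils::head(x$coords, 4))
  invisible(x)
}

#' Per-node coordinates of an embedding
#'
#' @param x A `hyperbolic_embedding` object.
#' @param ... Unused.
#' @return A tibble with columns `node`, `rank` (degree rank), `r`, `theta`.
#' @export
tidy.hyperbolic_embedding <- function(x, ...) x$coords

#' One-row summary of an embedding
#'
#' @param x A `hyperbolic_embedding` object.
#' @param ... Unused.
#' @return A one-row tibble: method, node count, the parameters used, the
#'   replay log-likelihood (likelihood-based methods) and runtime seconds.
#' @export
glance.hyperbolic_embedding <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n = nrow(x$coords),
    gamma = x$params$gamma %||% NA_real_,
    temp = x$params$temp %||% NA_real_,
    window = x$params$window %||% NA_real_,
    loglik = x$loglik %||% NA_real_,
    runtime = x$runtime %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an embedding in the hyperbolic disc
#'
#' Draws nodes at their native polar coordinates (optionally with edges),
#' coloured by angle so that angular neighbourhoods are easy to spot.
#'
#' @param object A `hyperbolic_embedding` object.
#' @param graph Optional igraph object; if supplied, edges are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyperbolic_embedding <- function(object, graph = NULL, ...) {
  co <- object$coords
  df <- tibble::tibble(x = co$r * cos(co$theta), y = co$r * sin(co$theta),
                       theta = co$theta)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(graph)) {
    al <- align_coords(co, graph)
    el <- igraph::as_edgelist(graph, names = FALSE)
    seg <- tibble::tibble(
      x = al$r[el[, 1]] * cos(al$theta[el[, 1]]),
      y = al$r[el[, 1]] * sin(al$theta[el[, 1]]),
      xend = al$r[el[, 2]] * cos(al$theta[el[, 2]]),
      yend = al$r[el[, 2]] * sin(al$theta[el[, 2]])
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linewidth = 0.1, alpha = 0.2, colour = "grey50")
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$theta), size = 1) +
    ggplot2::scale_colour_gradientn(
      colours = c("#E41A1C", "#FF7F00", "#4DAF4A", "#377EB8", "#984EA3", "#E41A1C"),
      guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s embedding", object$method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

# ---- routing reports -------------------------------------------------------

new_routing_report <- function(pairs, n_pairs) {
  succ <- sum(pairs$delivered)
  obj <- list(
    pairs = pairs,
    n_pairs = n_pairs,
    successes = succ,
    success_rate = succ / n_pairs,
    hop_stretches = pairs$stretch[pairs$delivered],
    mean_stretch = if (succ > 0) mean(pairs$stretch[pairs$delivered]) else NA_real_
  )
  class(obj) <- "routing_report"
  obj
}

#' @export
print.routing_report <- function(x, ...) {
  cat(sprintf("Greedy routing: %d/%d delivered (%.1f%%), mean hop stretch %.3f\n",
              x$successes, x$n_pairs, 100 * x$success_rate, x$mean_stretch))
  invisible(x)
}

#' Per-pair routing outcomes
#' @param x A `routing_report` object.
#' @param ... Unused.
#' @return A tibble with one row per source-target pair: `source`,
#'   `target`, `delivered`, `greedy_length`, `shortest_length`, `stretch`.
#' @export
tidy.routing_report <- function(x, ...) x$pairs

#' One-row routing summary
#' @param x A `routing_report` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `successes`, `success_rate`,
#'   `mean_stretch`.
#' @export
glance.routing_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, successes = x$successes,
                 success_rate = x$success_rate, mean_stretch = x$mean_stretch)
}

#' Histogram of hop stretches of successful deliveries
#' @param object A `routing_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.routing_report <- function(object, ...) {
  df <- tibble::tibble(stretch = object$hop_stretches)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stretch)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 1,
                            fill = "#377EB8", colour = "white") +
    ggplot2::labs(
      x = "hop stretch (greedy / shortest path length)", y = "deliveries",
      title = sprintf("%.1f%% delivered, mean stretch %.3f",
                      100 * object$success_rate, object$mean_stretch)) +
    ggplot2::theme_minimal()
}

# ---- connection-probability curves ----------------------------------------

#' Plot a connection-probability curve
#' @param object A tibble returned by [connection_probability_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance,
                                       y = .data$fraction_connected)) +
    ggplot2::geom_line(colour = "#377EB8") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "hyperbolic distance (bin centre)",
                  y = "fraction of pairs connected") +
    ggplot2::theme_minimal()
}

# ---- temperature fits ------------------------------------------------------

new_temperature_fit <- function(cbar_real, cbar_zero, t_est, n_replicas, params) {
  structure(list(cbar_real = cbar_real, cbar_zero = cbar_zero,
                 t_est = t_est, n_replicas = n_replicas, params = params),
            class = "temperature_fit")
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat(sprintf(
    "Temperature fit: T = %.3f (clustering %.3f vs %.3f in %d cold PS replicas)\n",
    x$t_est, x$cbar_real, x$cbar_zero, x$n_replicas))
  invisible(x)
}

#' One-row temperature-fit summary
#' @param x A `temperature_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `t_est`, `cbar_real`, `cbar_zero`,
#'   `n_replicas`.
#' @export
glance.temperature_fit <- function(x, ...) {
  tibble::tibble(t_est = x$t_est, cbar_real = x$cbar_real,
                 cbar_zero = x$cbar_zero, n_replicas = x$n_replicas)
}
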