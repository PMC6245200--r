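#' Width of the angular refinement window
#'
#' The window inside which LaBNE+HM lets HyperMap refine each draft angle.
#' Narrow windows suit strongly clustered (cold) networks where the
#' spectral draft is already accurate; wider windows suit sparser, hotter
#' networks. `"linear"` uses `w = 2*pi*T`, `"quadratic"` uses
#' `w = 2*pi*T^2`; both are floored at `pi/36` so that a cold network still
#' probes a minimal window. `"manual"` returns `window` unchanged.
#'
#' @param temp Network temperature in `[0, 1)`.
#' @param policy `"manual"`, `"linear"`, or `"quadratic"`.
#' @param window Window width in radians (required for `"manual"`),
#'   in `(0, 2*pi]`.
#' @return Window width in radians.
#' @examples
#' choose_window(0.5, "linear")      # pi
#' choose_window(0.5, "quadratic")   # pi/2
#' choose_window(0.3, "manual", window = pi / 6)
#' @export
choose_window <- function(temp, policy = c("manual", "linear", "quadratic"),
                          window = NULL) {
  policy <- match.arg(policy)
  stopifnot(temp >= 0, temp < 1)
  if (policy == "manual") {
    if (is.null(window)) stop("manual policy requires `window`", call. = FALSE)
    stopifnot(window > 0, window <= 2 * pi)
    return(window)
  }
  w <- if (policy == "linear") 2 * pi * temp else 2 * pi * temp^2
  max(w, pi / 36)
}

#' Hybrid hyperbolic embedding: spectral draft + likelihood refinement
#'
#' LaBNE+HM first drafts node positions with the fast spectral embedding
#' ([labne_embed()]) and then hands the draft to HyperMap
#' ([hypermap_embed()]), which refines each angle within a window `w`
#' around its draft value. With `w` near 0 the result behaves like LaBNE;
#' with `w` near `2*pi` it behaves like full HyperMap.
#'
#' The refinement likelihood needs a positive working temperature; for
#' `temp = 0` inputs, refinement runs at `T = 0.1` (window selection still
#' uses the supplied `temp`) and a message is emitted.
#'
#' @inheritParams hypermap_embed
#' @param temp Network temperature of the input in `[0, 1)` (estimate with
#'   [estimate_temperature()] if unknown).
#' @param policy Window policy, see [choose_window()].
#' @param window Window width in radians (for `policy = "manual"`).
#' @param ... Passed to [labne_embed()] (e.g. `respread`).
#' @return A `hyperbolic_embedding` object with the refined coordinates;
#'   the LaBNE draft is kept in `$draft` for diagnostics.
#' @examples
#' net <- sample_ps(100, m = 4, gamma = 2.5, temp = 0.3, seed = 5)
#' emb <- labne_hm_embed(net$graph, gamma = 2.5, temp = 0.3,
#'                       policy = "manual", window = pi / 6, seed = 5)
#' glance(emb)
#' @export
labne_hm_embed <- function(graph, gamma, temp,
                           policy = c("manual", "linear", "quadratic"),
                           window = NULL, k_speedup = 10, seed = NULL, ...) {
  t0 <- proc.time()[["elapsed"]]
  policy <- match.arg(policy)
  w <- choose_window(temp, policy, window)
  working_temp <- temp
  if (temp <= 0) {
    working_temp <- 0.1
    message("temp = 0: refining at working temperature T = 0.1")
  }
  draft <- labne_embed(graph, gamma = gamma, ...)
  draft_theta <- align_coords(draft$coords, graph)$theta
  refined <- hypermap_embed(graph, gamma = gamma, temp = working_temp,
                            k_speedup = k_speedup,
                            init_angles = draft_theta, window = w,
                            seed = seed)
  new_hyperbolic_embedding(
    method = "labne_hm", coords = refined$coords,
    params = list(gamma = gamma, temp = temp, working_temp = working_temp,
                  window = w, policy = policy, k_speedup = k_speedup,
                  seed = seed),
    extras = list(
      loglik = refined$loglik,
      loglik_init = refined$loglik_init,
      loglik_by_rank = refined$loglik_by_rank,
      loglik_center_by_rank = refined$loglik_center_by_rank,
      draft = draft$coords,
      runtime = proc.time()[["elapsed"]] - t0
    )
  )
}
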