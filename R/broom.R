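# broom-style accessors for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a yield model
#'
#' One row per epoch with the data-term losses in standardized units
#' (`mse`, `nll`, their blend `objective`; the L2 penalty is never included)
#' and the learning rate in force.
#'
#' @param x A fitted [yieldnet()] model.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `mse`, `nll`, `objective`, `lr`.
#' @export
tidy.yieldnet <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted yield model
#'
#' @param x A fitted [yieldnet()] model.
#' @param ... Unused.
#' @return A one-row tibble: training size, blend weight, schedule, final
#'   losses and the parameter count.
#' @export
glance.yieldnet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_train = x$n_train,
    lambda = x$config$lambda,
    epochs = x$config$epochs,
    batch_size = x$config$batch_size,
    final_mse = h$mse[nrow(h)],
    final_nll = h$nll[nrow(h)],
    final_objective = h$objective[nrow(h)],
    n_parameters = sum(vapply(x$params$w, length, numeric(1)))
  )
}
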