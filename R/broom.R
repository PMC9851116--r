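# broom-style accessors.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.mcac_fit <- function(x, ...) x$log

#' @export
glance.mcac_fit <- function(x, ...) {
  tibble(epochs = nrow(x$log),
         best_epoch = x$best_epoch,
         best_train_loss = x$best_loss,
         final_train_accuracy = tail(x$log$train_accuracy, 1),
         n_parameters = n_parameters(x$model),
         pretrained = x$pretrained,
         n_train_patients = length(x$split$train_patients),
         n_test_patients = length(x$split$test_patients))
}

#' @export
glance.fvep_autoencoder <- function(x, ...) {
  tibble(epochs = max(x$log$epoch),
         init_mse = x$log$mse[x$log$epoch == 0],
         final_mse = tail(x$log$mse, 1))
}

#' @export
tidy.fvep_autoencoder <- function(x, ...) x$log
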