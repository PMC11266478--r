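#' Ablation case table
#'
#' The seven standard component combinations: the full model plus six cases
#' switching off the unsupervised superpixelwise-PCA reduction, the CBAM
#' attention gates, the 3D+2D CNN feature extractor, and/or the
#' tokenizer + transformer-encoder pair. Disabled modules are replaced by
#' documented substitutes: without SuperPCA the patches come from a
#' global-image PCA to the same band count; without CBAM both gates are
#' fixed at 1; without the CNN the raw reduced patch is projected
#' per-position to the channel width before tokenization; without the
#' tokenizer/TE a two-layer fully connected head classifies the flattened
#' feature map.
#'
#' @return data frame with columns `name`, `use_superpca`, `use_cbam`,
#'   `use_cnn`, `use_tokenizer_te`.
#' @export
ablation_cases <- function() {
  data.frame(
    name = c("Case 1", "Case 2", "Case 3", "Case 4", "Case 5", "Case 6",
             "Full"),
    use_superpca     = c(TRUE,  FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE),
    use_cbam         = c(FALSE, TRUE,  FALSE, FALSE, TRUE,  FALSE, TRUE),
    use_cnn          = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    use_tokenizer_te = c(TRUE,  TRUE,  TRUE,  FALSE, FALSE, TRUE,  TRUE),
    stringsAsFactors = FALSE)
}

#' Run the component-ablation experiment
#'
#' Trains one model variant per ablation case under a small-sample protocol
#' (default 5% training fraction) and reports test-set AA, OA and
#' Kappa x 100 per case, averaged over `n_seeds` split/training seeds.
#'
#' @param patches_super patch set extracted from the superpixelwise-PCA
#'   reduced cube.
#' @param patches_global patch set extracted from a global-PCA reduced cube
#'   (same geometry); used by the cases without SuperPCA.
#' @param cases data frame as from [ablation_cases()].
#' @param train_fraction training fraction (default 0.05).
#' @param epochs,batch_size,lr training hyperparameters for every case.
#' @param seed base seed; seed + r - 1 is used for repetition r.
#' @param n_seeds number of repetitions averaged.
#' @param config_args extra arguments passed to [sst_config()] (e.g. a
#'   reduced geometry).
#' @param ... further training arguments passed to [train_sst()] (e.g.
#'   `lr_decay`).
#' @return data frame: one row per case with mean AA, OA, Kappa x 100.
#' @export
run_ablation <- function(patches_super, patches_global = patches_super,
                         cases = ablation_cases(), train_fraction = 0.05,
                         epochs = 40, batch_size = 32, lr = 2e-3, seed = 1,
                         n_seeds = 1, config_args = list(), ...) {
  stopifnot(inherits(patches_super, "patch_set"))
  if (!all(c("name", "use_superpca", "use_cbam", "use_cnn",
             "use_tokenizer_te") %in% names(cases))) {
    stop("malformed ablation case table")
  }
  nz <- max(patches_super$labels, patches_global$labels)
  acc <- matrix(0, nrow(cases), 3,
                dimnames = list(cases$name, c("AA", "OA", "Kappa100")))
  for (r in seq_len(n_seeds)) {
    sr <- seed + r - 1L
    for (i in seq_len(nrow(cases))) {
      ps <- if (cases$use_superpca[i]) patches_super else patches_global
      idx <- split_indices(ps$labels, train_fraction, seed = sr)
      cfg <- do.call(sst_config, c(list(
        s = ps$s, b = ps$b, n_classes = nz,
        use_cbam = cases$use_cbam[i], use_cnn = cases$use_cnn[i],
        use_tokenizer = cases$use_tokenizer_te[i]), config_args))
      model <- train_sst(ps[idx$train], cfg, epochs = epochs,
                         batch_size = batch_size, lr = lr, seed = sr, ...)
      pred <- predict(model, ps[idx$test])
      acc[i, ] <- acc[i, ] + metric_row(ps$labels[idx$test], pred, nz)
    }
  }
  out <- as.data.frame(acc / n_seeds)
  out$AA <- 100 * out$AA; out$OA <- 100 * out$OA
  cbind(cases["name"], out)
}
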