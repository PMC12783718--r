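# A tiny separable classification problem and matching model/protocol
# configs, shared by the classifier and saliency tests.

tiny_problem <- function(n_per_class = 12, seed = 4) {
  cached(sprintf("tiny_%d_%d", n_per_class, seed), {
    ids <- c(sprintf("A%02d", seq_len(n_per_class)),
             sprintf("B%02d", seq_len(n_per_class)))
    recs <- tibble::tibble(specimen_id = ids,
                           clade = rep(c("Northern", "Southern"),
                                       each = n_per_class),
                           location = "L1")
    imgs <- cladescan:::with_seed(seed, {
      vapply(seq_along(ids), function(i) {
        base <- if (i <= n_per_class) 0.85 else 0.15
        base + rnorm(256, 0, 0.02)
      }, numeric(256))
    })
    colnames(imgs) <- ids
    list(records = recs, images = imgs)
  })
}

tiny_model_config <- function(seed = 1) {
  model_config(conv_channels = c(4L, 8L), dense_units = 8L, input_size = 16L,
               epochs = 12L, batch_size = 8L, learning_rate = 5e-3, seed = seed)
}

tiny_protocol <- function() {
  protocol_config(n_train_per_class = 6, n_val_per_class = 2,
                  n_even_test_per_class = 3, n_iterations = 2, base_seed = 9)
}

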