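# Small fixtures shared across test files; everything is built in code.

tiny_spec <- function(seed = 7, n_train = 24, n_val = 12, ...) {
  synthetic_spec(n_classes = 3, n_views = 4, informative_views = c(1, 2),
                 feature_dim = 5, n_train = n_train, n_val = n_val,
                 seed = seed, ...)
}

tiny_model <- function(ds, seed = 3, d = 8, n_heads = 4, n_queries = 2) {
  enc <- encoder_config(input_mode = "feature",
                        feature_dim = ds$spec$feature_dim,
                        embedding_dim = d, hidden_dim = 6,
                        n_queries = n_queries)
  fus <- fusion_config(n_classes = length(ds$class_names), d = d,
                       n_heads = n_heads)
  init_model(enc, fus, gate_config(), ds$view_names, ds$class_names,
             seed = seed)
}

# Published sweep rows (Calyptratae-style, 8 views, 11.31 G baseline)
calyptratae_rows <- function() {
  tibble::tibble(
    lambda = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    view_count = c(8L, 8L, 7L, 5L, 3L, 1L),
    accuracy = c(87.04, 87.04, 87.04, 86.11, 84.26, 83.33)
  )
}

# Published sweep rows (Culicidae-style, 11 views, 49.56 G baseline)
culicidae_rows <- function() {
  tibble::tibble(
    lambda = c(0.00, 0.05, 0.10, 0.15, 0.20, 0.25),
    view_count = c(11L, 9L, 8L, 3L, 2L, 1L),
    accuracy = c(100.00, 100.00, 100.00, 100.00, 100.00, 97.18)
  )
}

# random RGB test image
rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}
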