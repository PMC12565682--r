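# Shared fixtures.  Everything is generated in code; the only files used are
# the package's bundled plain-text data.

default_tax <- load_taxonomy()

# a small, fast phantom cohort for pipeline-level tests
small_cohort <- function(n = 30, size = 64, abnormal = 0.5, seed = 42,
                         noise = TRUE) {
  cfg <- phantom_config(
    n_specimens = n, image_size = c(size, size), abnormal_fraction = abnormal,
    noise_sigma = if (noise) 0.02 else 0,
    center_jitter = if (noise) 0.1 else 0,
    seed = seed
  )
  generate_dataset(cfg, default_tax)
}

# brute-force all-pairs AUC oracle (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# minimal record constructor
rec <- function(id, view, pixels) {
  list(specimen_id = id, view = view, pixels = pixels)
}
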