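# Shared fixtures, all built in code at test time.

# compact 32^3 spec for unit tests where geometry details don't matter
small_spec <- function(...) {
  phantom_spec(shape = c(32L, 32L, 32L), voxel_size = c(2, 2, 2), ...)
}

# wrap a sample vector as a degenerate (n x 1 x 1) volume + all-true mask so
# build_histogram can bin it
hist_from_samples <- function(x, n_bins = 128L) {
  vol <- volume3d(array(x, dim = c(length(x), 1L, 1L)))
  build_histogram(vol, binary_mask(array(TRUE, dim = c(length(x), 1L, 1L))),
                  n_bins)
}

# draws from a two-component Gaussian mixture with exact component counts
mixture_samples <- function(n, mu1, s1, mu2, s2, w1) {
  n1 <- round(w1 * n)
  c(stats::rnorm(n1, mu1, s1), stats::rnorm(n - n1, mu2, s2))
}

# hand-built bimodal_fit for tests that exercise downstream operations alone
fake_fit <- function(mu_low, sigma_low, mu_high = mu_low + 10 * sigma_low,
                     sigma_high = sigma_low, amp_low = 1, amp_high = 1) {
  structure(list(amp_low = amp_low, mu_low = mu_low, sigma_low = sigma_low,
                 amp_high = amp_high, mu_high = mu_high,
                 sigma_high = sigma_high, rss = 0, converged = TRUE,
                 unimodal_fallback = FALSE, n_restarts_used = 0L,
                 optimizer_info = 1L),
            class = "bimodal_fit")
}

# tiny two-region atlas on an n^3 grid: label 1 = first `k` voxels,
# label 2 = cerebellum stand-in = next `k` voxels
tiny_atlas <- function(n = 6L, k = 4L) {
  lab <- array(0, dim = c(n, n, n))
  lab[seq_len(k)] <- 1
  lab[k + seq_len(k)] <- 2
  region_map <- c(stats::setNames(rep(list(1L), 8L), persi_regions()),
                  list(whole_cerebellum = 2L))
  # the 8 regions deliberately share one label; silence the overlap warning
  suppressWarnings(load_atlas(volume3d(lab), region_map))
}
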