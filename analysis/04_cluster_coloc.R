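#!/usr/bin/env Rscript
# Clustering and colocalization: the local-variance statistic separates
# punctate from diffuse synthetic nuclei; Manders coefficients quantify
# channel overlap on the banded phantom.  Writes results/variance_test.csv
# and results/coloc.csv.

suppressPackageStartupMessages(library(chromodyn))

dir.create("results", showWarnings = FALSE)
set.seed(1)

# synthetic nuclei: a diffuse fluorophore vs one forming bright punctae,
# equal mean intensity, read-noise level alike
make_nucleus <- function(clustered) {
  img <- matrix(pmax(rnorm(64 * 64, 100, 12), 0), 64, 64)
  if (clustered) {
    centers <- cbind(sample(8:56, 25, TRUE), sample(8:56, 25, TRUE))
    for (k in seq_len(nrow(centers)))
      img[centers[k, 1] + (-1:1), centers[k, 2] + (-1:1)] <-
        img[centers[k, 1] + (-1:1), centers[k, 2] + (-1:1)] + 110
    img <- img * (100 / mean(img))
  }
  img
}
mv <- function(img) local_variance_map(img, radius = 2)$mean_nuclear_variance
diffuse <- vapply(1:29, function(i) mv(make_nucleus(FALSE)), numeric(1))
punctate <- vapply(1:32, function(i) mv(make_nucleus(TRUE)), numeric(1))

ts <- two_sample_test(diffuse, punctate)
tv <- data.frame(group = c("diffuse", "punctate"),
                 mean_variance = c(ts$mean[["a"]], ts$mean[["b"]]),
                 sd = c(ts$sd[["a"]], ts$sd[["b"]]),
                 n = c(ts$n[["a"]], ts$n[["b"]]))
write.csv(tv, "results/variance_test.csv", row.names = FALSE)
cat(sprintf("Mean nuclear variance (radius 2): diffuse %.0f +/- %.0f (n=%d) vs punctate %.0f +/- %.0f (n=%d)\n",
            ts$mean[["a"]], ts$sd[["a"]], ts$n[["a"]],
            ts$mean[["b"]], ts$sd[["b"]], ts$n[["b"]]))
cat(sprintf("Welch t = %.2f, p = %.2g (pooled p = %.2g)\n",
            ts$t, ts$p_welch, ts$p_pooled))

# colocalization on the banded phantom: a remodeler-like channel (bright in
# open chromatin) against the histone channel
ph <- render_nucleus_phantom(phantom_spec(seed = 1L))
mid <- ceiling(dim(ph$image)[3] / 2)
h2b <- ph$image[, , mid]
brm <- 255 - h2b
nucleus <- ph$labels[, , mid] > 1L
mc <- manders_coefficients(brm, h2b, mask = nucleus)
co <- data.frame(M1 = mc$M1, M2 = mc$M2, tau_a = mc$tau_a, tau_b = mc$tau_b)
write.csv(co, "results/coloc.csv", row.names = FALSE)
cat(sprintf("Manders on anti-correlated channels: M1 = %.2f, M2 = %.2f (Otsu thresholds)\n",
            mc$M1, mc$M2))
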