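# Independent reference implementations used as oracles. Deliberately naive
# (scalar double loops, explicit boundary clamping) so they share no code
# with the vectorized package paths.

# one anisotropic-diffusion step evaluated pixel by pixel
oracle_diffuse_step <- function(img, kappa, lam) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gN <- img[max(r - 1, 1), c] - img[r, c]
    gS <- img[min(r + 1, nr), c] - img[r, c]
    gE <- img[r, min(c + 1, nc)] - img[r, c]
    gW <- img[r, max(c - 1, 1)] - img[r, c]
    flux <- exp(-(gN / kappa)^2) * gN + exp(-(gS / kappa)^2) * gS +
            exp(-(gE / kappa)^2) * gE + exp(-(gW / kappa)^2) * gW
    out[r, c] <- img[r, c] + lam * flux
  }
  out
}

# confusion counts and the eight metrics from an explicit pixel loop
oracle_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  sdiv <- function(n, d, e) if (d > 0) n / d else e
  precision <- sdiv(tp, tp + fp, if (fn == 0) 1 else 0)
  recall    <- sdiv(tp, tp + fn, if (fp == 0) 1 else 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       iou = sdiv(tp, tp + fp + fn, 1),
       dice = sdiv(2 * tp, 2 * tp + fp + fn, 1),
       accuracy = (tp + tn) / length(pred),
       precision = precision, recall = recall,
       f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall)
            else if (tp + fp + fn == 0) 1 else 0,
       specificity = sdiv(tn, tn + fp, if (fn == 0) 1 else 0))
}

random_byte_image <- function(nr, nc) {
  m <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  storage.mode(m) <- "integer"
  m
}

random_mask <- function(nr, nc, p = 0.5) {
  m <- matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
  storage.mode(m) <- "integer"
  m
}

total_variation <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
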