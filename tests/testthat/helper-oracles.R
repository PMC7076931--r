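# Independent oracles and small fixture builders shared across tests.

# high-precision PLN pmf by direct adaptive quadrature on the rate scale
pln_oracle <- function(n, mu, sigma) {
  f <- function(lam) dpois(n, lam) * dlnorm(lam, mu, sigma)
  split <- max(n, 1)
  r1 <- integrate(f, 0, split, rel.tol = 1e-12, abs.tol = 1e-300,
                  stop.on.error = FALSE)
  r2 <- integrate(f, split, Inf, rel.tol = 1e-12, abs.tol = 1e-300,
                  stop.on.error = FALSE)
  r1$value + r2$value
}

# exhaustive MIC: every grid over both axes (cuts between distinct values),
# any shape with nx * ny <= B
mic_exhaustive_oracle <- function(x, y, B) {
  n <- length(x)
  mi_grid <- function(cx, cy) {
    gx <- findInterval(x, cx)
    gy <- findInterval(y, cy)
    tab <- table(gx, gy) / n
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py))
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    mi
  }
  bx <- sort(unique(x)); by <- sort(unique(y))
  cutx <- (head(bx, -1) + tail(bx, -1)) / 2
  cuty <- (head(by, -1) + tail(by, -1)) / 2
  best <- 0
  for (nx in 2:floor(B / 2)) for (ny in 2:floor(B / nx)) {
    if (nx - 1 > length(cutx) || ny - 1 > length(cuty)) next
    for (cxs in combn(length(cutx), nx - 1, simplify = FALSE))
      for (cys in combn(length(cuty), ny - 1, simplify = FALSE)) {
        v <- unname(mi_grid(c(-Inf, cutx[cxs]), c(-Inf, cuty[cys]))) /
          log2(min(nx, ny))
        if (v > best) best <- v
      }
  }
  unname(best)
}

# normalized MI of the fixed equipartition grid (lower bound on MIC)
mic_equipartition_grid <- function(x, y, nx, ny) {
  n <- length(x)
  cutq <- function(v, k) {
    qs <- unique(quantile(v, probs = seq(0, 1, length.out = k + 1)[-c(1, k + 1)]))
    findInterval(v, qs, left.open = TRUE)
  }
  gx <- cutq(x, nx); gy <- cutq(y, ny)
  tab <- table(gx, gy) / n
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  mi / log2(min(nx, ny))
}

# a tiny deterministic otu_table: 4 samples x 5 OTUs, two sites / regions
tiny_table <- function() {
  cnt <- matrix(c(5L, 0L, 3L, 1L, 0L,
                  2L, 4L, 0L, 1L, 0L,
                  0L, 1L, 6L, 2L, 0L,
                  3L, 3L, 3L, 3L, 0L),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), paste0("otu", 1:5)))
  otu_table(cnt, site = c("A", "A", "B", "B"),
            region = c("r1", "r1", "r2", "r2"), domain = "bacteria")
}
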