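# Independent oracles used to cross-check the analytical implementations.

# Fractional activity from the mass-balance equilibrium, solved by bisection
# on the free-enzyme concentration. Independent of the closed-form quadratic
# used by morrison_fraction().
morrison_oracle <- function(e0, i0, ki) {
  if (i0 == 0) return(1)
  f <- function(E) E * (i0 - e0 + E) - ki * (e0 - E)
  lo <- max(0, e0 - i0)
  hi <- e0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  ((lo + hi) / 2) / e0
}

# Closed-form exposed area of sphere 1 (radius r1) partially occluded by
# sphere 2 (radius r2) at centre distance d: full sphere minus the buried
# spherical cap.
two_sphere_exposed_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  4 * pi * r1^2 - 2 * pi * r1 * h1
}

# O(n^2) loop-based contact scan, deliberately naive.
contacts_bruteforce <- function(atoms, cutoff) {
  hits <- list()
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (atoms$chain[i] == atoms$chain[j] && atoms$resno[i] == atoms$resno[j]) next
      dd <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                   (atoms$z[i] - atoms$z[j])^2)
      if (dd <= cutoff) hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}

# random small atom cluster for structure tests
random_cluster <- function(n, spread = 6, elements = c("C", "N", "O", "S")) {
  tibble::tibble(
    chain = "A",
    resno = rep(seq_len(ceiling(n / 4)), each = 4L, length.out = n),
    resid = "ALA",
    elety = sample(c("N", "CA", "C", "O", "CB", "CG"), n, replace = TRUE),
    element = sample(elements, n, replace = TRUE),
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread)
  )
}
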