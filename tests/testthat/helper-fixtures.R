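# Shared test helpers: tiny deterministic fixtures built in code.

tmp_file <- function(ext) tempfile(fileext = ext)

# brute-force substring counter: independent oracle for scan_literal
brute_count_substr <- function(s, lit) {
  n <- nchar(s); k <- nchar(lit)
  if (k > n) return(0L)
  sum(vapply(seq_len(n - k + 1L), function(i)
    substr(s, i, i + k - 1L) == lit, logical(1)))
}

# independent Shrake-Rupley oracle: plain double loop over a different,
# denser deterministic point set (offset golden-angle spiral)
oracle_sasa_total <- function(atoms, probe = 1.4, n_points = 9600L) {
  radii_tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  radii <- unname(radii_tab[toupper(atoms$element)]) + probe
  i_pt <- seq_len(n_points) - 0.25          # offset differs from package lattice
  phi <- acos(1 - 2 * i_pt / n_points)
  theta <- pi * (1 + sqrt(5)) * i_pt + 0.7
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  total <- 0
  for (i in seq_len(nrow(atoms))) {
    ci <- as.numeric(atoms[i, c("x", "y", "z")])
    acc <- 0L
    for (p in seq_len(n_points)) {
      pt <- ci + radii[i] * pts[p, ]
      blocked <- FALSE
      for (j in seq_len(nrow(atoms))) {
        if (j == i) next
        cj <- as.numeric(atoms[j, c("x", "y", "z")])
        if (sum((pt - cj)^2) < radii[j]^2) { blocked <- TRUE; break }
      }
      if (!blocked) acc <- acc + 1L
    }
    total <- total + 4 * pi * radii[i]^2 * acc / n_points
  }
  total
}

# random rigid-body transform helper (caller controls the RNG seed)
random_isometry <- function(model) {
  elfscan::transform_model(model, translation = stats::runif(3, -50, 50))
}

expect_same_bridges <- function(sb, truth) {
  expect_equal(nrow(sb), nrow(truth))
  got <- sb[order(sb$basic_res_seq, sb$kind),
            c("basic_chain", "basic_res_seq", "partner_chain",
              "partner_res_seq", "kind")]
  want <- truth[order(truth$basic_res_seq, truth$kind), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

expect_same_pairings <- function(bp, truth) {
  expect_equal(length(bp), length(truth))
  for (k in seq_along(truth)) {
    expect_equal(bp[[k]]$orientation, truth[[k]]$orientation)
    expect_equal(bp[[k]]$registry, truth[[k]]$registry)
  }
}
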