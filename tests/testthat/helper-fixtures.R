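# Shared fixtures, generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# default-grid phantom pair (64x64x32 @ 3 mm)
fx_pair <- function() fixture("pair", function() make_phantom(phantom_spec(seed = 3)))

# clinical-resolution phantom pair (1.5 mm), for discretisation-sensitive checks
fx_pair_fine <- function() fixture("pair_fine", function()
  make_phantom(phantom_spec(shape = c(128, 128, 64),
                            spacing_mm = c(1.5, 1.5, 1.5), seed = 3)))

fx_dose <- function() fixture("dose", function() make_planning_dose(fx_pair()))

# small random binary mask helpers
random_mask <- function(dim3, p = 0.2) {
  array(stats::runif(prod(dim3)) < p, dim3)
}

random_blob <- function(dim3, n_seeds = 2) {
  arr <- array(FALSE, dim3)
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(dim3, function(n) sample.int(n, 1))
    r <- sample(2:4, 1)
    idx <- which(array(TRUE, dim3), arr.ind = TRUE)
    d2 <- colSums((t(idx) - c0)^2)
    arr[d2 <= r^2] <- TRUE
  }
  arr
}

# Brute-force oracle for directed surface distances: R double loop with the
# same surface definition (face-adjacent outside voxel or array boundary).
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    if (i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]) {
      out[i, j, k] <- TRUE; next
    }
    if (!mask[i - 1, j, k] || !mask[i + 1, j, k] ||
        !mask[i, j - 1, k] || !mask[i, j + 1, k] ||
        !mask[i, j, k - 1] || !mask[i, j, k + 1]) out[i, j, k] <- TRUE
  }
  out
}

oracle_directed <- function(a, b, spacing) {
  sa <- which(oracle_surface(a), arr.ind = TRUE)
  sb <- which(oracle_surface(b), arr.ind = TRUE)
  sa_mm <- sweep(sa, 2, spacing, "*")
  sb_mm <- sweep(sb, 2, spacing, "*")
  vapply(seq_len(nrow(sa_mm)), function(r) {
    sqrt(min(colSums((t(sb_mm) - sa_mm[r, ])^2)))
  }, 0)
}

# Hard-histogram mutual information oracle (natural log), equal-width bins
# on [0, 1].
oracle_mi <- function(a, b, bins) {
  ia <- pmin(pmax(floor(a * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor(b * bins) + 1, 1), bins)
  P <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  P <- P / sum(P)
  pa <- rowSums(P); pb <- colSums(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H(pa) + H(pb) - H(P)
}

oracle_nmi <- function(a, b, bins) {
  ia <- pmin(pmax(floor(a * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor(b * bins) + 1, 1), bins)
  P <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  P <- P / sum(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(rowSums(P)) + H(colSums(P))) / H(P)
}

# training-pair constructor from a ground-truth phantom pair
as_train_pair <- function(p) {
  list(fixed = clip_normalize(p$planning$image),
       moving = clip_normalize(p$daily$image),
       fixed_labels = p$planning$labels,
       moving_labels = p$daily$labels)
}

organ_dsc <- function(fixed_labels, labels) {
  vapply(2:4, function(code) dsc(fixed_labels$data == code,
                                 labels$data == code), 0)
}
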