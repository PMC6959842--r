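# internal helpers shared across modules

# Run `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Every stochastic entry point in the
# package routes through this so that no call mutates global RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coords array helpers -------------------------------------------------------

# frames x atoms x 3 array -> frames x 3N matrix (x1,y1,z1,x2,...), bio3d order
coords_to_xyz <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  m <- matrix(aperm(coords, c(3, 2, 1)), nrow = nf, ncol = 3 * na, byrow = TRUE)
  m
}

# frames x 3N matrix -> frames x atoms x 3 array
xyz_to_coords <- function(xyz) {
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  aperm(array(t(xyz), dim = c(3, na, nf)), c(3, 2, 1))
}

# Kabsch: proper rotation R (det +1) and translation minimizing RMSD of
# mobile onto fixed (both n x 3).  Returns list(R, t) so that
# fitted = mobile %*% R + t (row-vector convention).
kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  H <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = cf - drop(cm %*% R))
}

deg <- function(rad) rad * 180 / pi

vec_norm <- function(v) sqrt(sum(v^2))
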