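# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Finite-difference (method of lines) solution of the 1-D diffusion equation
# with constant-concentration boundaries, via deSolve.
fd_diffusion_profile <- function(x_um, t_s, D, W, nx = 481) {
  dx <- W / (nx - 1)
  rhs <- function(t, y, p) {
    dy <- numeric(nx)
    dy[2:(nx - 1)] <- D * (y[3:nx] - 2 * y[2:(nx - 1)] + y[1:(nx - 2)]) / dx^2
    list(dy)
  }
  y0 <- c(1, rep(0, nx - 2), 1)
  out <- deSolve::ode(y0, c(0, t_s), rhs, NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-10)
  grid <- seq(0, W, length.out = nx)
  approx(grid, out[2, -1], xout = x_um)$y
}

# Slow reference 26-connectivity 3-D labeling (breadth-first search in R).
label3d_reference <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nxt <- 0L
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (i0 in which(mask)) {
    if (lab[i0] != 0L) next
    nxt <- nxt + 1L
    queue <- i0
    lab[i0] <- nxt
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      z <- (i - 1) %% dims[1] + 1
      y <- ((i - 1) %/% dims[1]) %% dims[2] + 1
      x <- (i - 1) %/% (dims[1] * dims[2]) + 1
      for (r in seq_len(nrow(nb))) {
        zz <- z + nb[r, 1]; yy <- y + nb[r, 2]; xx <- x + nb[r, 3]
        if (zz < 1 || zz > dims[1] || yy < 1 || yy > dims[2] ||
            xx < 1 || xx > dims[3]) next
        j <- zz + dims[1] * (yy - 1) + dims[1] * dims[2] * (xx - 1)
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Match recovered cells to ground-truth cells by nearest nucleus centroid.
match_to_truth <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$centroid_z_um - cells$centroid_z_um[i])^2 +
                (truth$centroid_y_um - cells$centroid_y_um[i])^2 +
                (truth$centroid_x_um - cells$centroid_x_um[i])^2)
  }, integer(1))
}

# A small noiseless stack shared by several imagequant tests.
small_noiseless_stack <- function(n_cells = 12, seed = 11,
                                  fractions = c(negative = 0.2,
                                                restricted = 0.3,
                                                secreting = 0.5), ...) {
  generate_cell_stack(
    phenotype_params(n_cells = n_cells, fractions = fractions,
                     shape = c(22, 180, 180), noise_sd = 0, ...),
    seed = seed)
}
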