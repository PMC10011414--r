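# shared fixtures: everything is generated in code at test time

toy_grid <- function(n = 20) grid_spec(n, n)

toy_stack <- function(n = 20, seed = 1, range_km = 5) {
  simulate_climate(grid_spec(n, n), climate_params(range_km = range_km),
                   seed = seed)
}

# a pa_mask with the given cells (column-major indices) set to one class
pa_with_cells <- function(grid, cells, class = "II") {
  m <- matrix(0L, grid$n_rows, grid$n_cols)
  m[cells] <- match(class, c("Ia", "Ib", "II", "III", "IV", "V", "VI"))
  pa_mask(grid, m)
}

# binary_range from a logical/0-1 matrix
range_from <- function(mat, id = "sp", scenario = "current") {
  binary_range(id, scenario, mat > 0)
}

# brute-force Moran's I with rook weights (independent double-sum oracle)
morans_i_brute <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- m - mean(m)
  num <- 0; w_sum <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        num <- num + x[r, cc] * x[r2, c2]
        w_sum <- w_sum + 1
      }
    }
  }
  (nr * nc / w_sum) * num / sum(x^2)
}

# two separable Gaussian clouds in d dimensions
separable_toy <- function(n = 200, d = 2, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * d, -2), ncol = d),
             matrix(rnorm(n / 2 * d, 2), ncol = d))
  colnames(x) <- paste0("v", seq_len(d))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
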