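# Shared fixtures and independent oracles.

# Build a system from explicit atoms and per-frame coordinates.
# coords: n_atoms x 3 matrix, or n_atoms x 3 x n_frames array.
point_system <- function(names, elements, charges, coords,
                         kinds = "protein", res_numbers = NULL,
                         groups = NULL) {
  n <- length(names)
  kinds <- rep_len(kinds, n)
  if (is.null(res_numbers)) res_numbers <- seq_len(n)
  atoms <- data.frame(
    name = names, element = elements, chain = "A",
    res_number = res_numbers,
    res_name = ifelse(kinds == "water", "HOH",
                      ifelse(kinds == "ligand", "LIG", "GLY")),
    kind = kinds, charge = charges, stringsAsFactors = FALSE
  )
  if (is.null(groups)) groups <- list(probe = 1L)
  molecular_system(atoms, coords, groups)
}

# Independent all-pairs minimum distance (plain double loop).
brute_min_dist <- function(xyz, a, b) {
  best <- Inf
  for (i in a) for (j in b) {
    best <- min(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  best
}

brute_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Gotoh global alignment with affine gaps (gap of length L costs
# open + L * ext), returning the two aligned character vectors.
# Independent of the package's Biostrings-based path.
gotoh_align <- function(a, b, submat, open = 10, ext = 4) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb)
      s <- submat[A[i - 1], B[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ra <- c(A[i - 1], ra); rb <- c("-", rb)
      state <- if (isTRUE(all.equal(X[i, j], M[i - 1, j] - open - ext))) 1 else 2
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j - 1], rb)
      state <- if (isTRUE(all.equal(Y[i, j], M[i, j - 1] - open - ext))) 1 else 3
      j <- j - 1
    }
  }
  list(a = ra, b = rb)
}

# Identity/similarity percentages from aligned vectors, counted
# independently of the package (no terminal-gap handling needed when the
# oracle alignments have none).
count_identity <- function(a, b, submat) {
  gap <- a == "-" | b == "-"
  n <- length(a)
  c(identity = 100 * sum(!gap & a == b) / n,
    similarity = 100 * sum(mapply(function(x, y) {
      if (x == "-" || y == "-") FALSE else submat[x, y] > 0
    }, a, b)) / n)
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

# Small rendered fixture shared by several tests.
small_render <- function(receptor = "MOR", n_frames = 40, n_replicates = 2,
                         seed = 11, ...) {
  spec <- synthetic_spec(receptor, n_frames = n_frames,
                         n_replicates = n_replicates, seed = seed, ...)
  template <- generate_template(spec)
  list(spec = spec, template = template,
       render = render_trajectory(template, spec))
}
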