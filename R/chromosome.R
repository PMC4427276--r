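# Binary encoding of pathway variables, sub-populations, cooperative
# chromosome assembly and the genetic operators.

#' Genetic operator settings
#'
#' @param population_size Members per sub-population (benchmark presets
#'   use 150).
#' @param bits_per_variable Sub-chromosome length L.  The default 16 bits
#'   give a resolution of (hi - lo)/65535, finer than the 4-decimal
#'   precision of the published best solutions on a 0-50 range.
#' @param crossover_points Number k of crossover cut points (k < L).
#' @param mutation_rate Probability that a chromosome is mutated at all
#'   (one uniformly chosen bit is then flipped).  The rate is
#'   per-individual, not per-bit.
#' @param elitism_count Best-credited members carried unchanged into the
#'   next generation of each sub-population.
#' @param immigrant_fraction Fraction of each new generation replaced by
#'   fresh uniform-random chromosomes (random immigrants).  Keeps
#'   sub-populations from collapsing onto one value, so that collaborator
#'   draws can still explore distant joint moves; set to 0 for a pure
#'   crossover-mutation generational cycle.
#' @param gray_code If `TRUE`, bit strings are interpreted as Gray code
#'   before decoding (standard binary by default).
#' @return A `genetic_config` list.
#' @export
genetic_config <- function(population_size = 150L, bits_per_variable = 16L,
                           crossover_points = 2L, mutation_rate = 0.3,
                           elitism_count = 1L, immigrant_fraction = 0.05,
                           gray_code = FALSE) {
  stopifnot(population_size >= 2L, bits_per_variable >= 2L,
            crossover_points >= 1L,
            crossover_points < bits_per_variable,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0L, elitism_count <= population_size,
            immigrant_fraction >= 0, immigrant_fraction <= 0.5)
  structure(list(population_size = as.integer(population_size),
                 bits_per_variable = as.integer(bits_per_variable),
                 crossover_points = as.integer(crossover_points),
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 immigrant_fraction = immigrant_fraction,
                 gray_code = isTRUE(gray_code)),
            class = "genetic_config")
}

gray_to_binary <- function(B) {
  # cumulative XOR along columns, vectorized over rows
  out <- B
  for (j in seq_len(ncol(B))[-1]) out[, j] <- bitwXor(out[, j - 1L], B[, j])
  out
}

# Decode an n x L 0/1 matrix to n reals on [lo, hi], most significant bit
# first: lo + int(bits) / (2^L - 1) * (hi - lo).
decode_matrix <- function(B, lo, hi, gray = FALSE) {
  L <- ncol(B)
  if (gray) B <- gray_to_binary(B)
  w <- 2^((L - 1L):0)
  ints <- drop(B %*% w)
  lo + ints / (2^L - 1) * (hi - lo)
}

#' Decode a bit string to a bounded real
#'
#' Maps the integer value of `bits` (most significant bit first) affinely
#' onto `[lo, hi]`: all-zero bits hit `lo` exactly, all-one bits hit `hi`
#' exactly, and the map is monotone in the integer value.
#'
#' @param bits Integer vector of 0/1 values.
#' @param lo,hi Bounds with `lo <= hi`.
#' @param gray Interpret `bits` as Gray code.
#' @return Decoded value in `[lo, hi]`.
#' @export
decode_bits <- function(bits, lo, hi, gray = FALSE) {
  stopifnot(length(bits) >= 1L, all(bits %in% c(0L, 1L)), lo <= hi)
  decode_matrix(matrix(as.integer(bits), nrow = 1L), lo, hi, gray = gray)
}

# Parity mask for k-point crossover: M[i, j] is 1 where pair i takes
# position j from the other parent.  cuts is a k x npair matrix of cut
# positions in 1..(L-1); a cut at c separates positions c and c + 1.
crossover_mask <- function(cuts, L) {
  np <- ncol(cuts)
  M <- matrix(0L, np, L)
  for (r in seq_len(nrow(cuts)))
    M <- M + outer(cuts[r, ], seq_len(L), "<")
  M %% 2L
}

draw_cuts <- function(k, np, L) {
  if (k == 1L) {
    matrix(sample.int(L - 1L, np, replace = TRUE), nrow = 1L)
  } else if (k == 2L) {
    c1 <- sample.int(L - 1L, np, replace = TRUE)
    r <- sample.int(L - 2L, np, replace = TRUE)
    rbind(c1, c2 = r + (r >= c1))
  } else {
    vapply(seq_len(np), function(i) sample.int(L - 1L, k), integer(k))
  }
}

# Crossover of paired rows: A and B are npair x L matrices (row i of A mates
# with row i of B).  Returns the two child matrices.
crossover_pairs <- function(A, B, k) {
  L <- ncol(A)
  M <- crossover_mask(draw_cuts(k, nrow(A), L), L)
  list(a = A * (1L - M) + B * M,
       b = B * (1L - M) + A * M)
}

#' k-point crossover of two bit strings
#'
#' Draws `k` distinct cut positions without replacement; segments between
#' cuts alternate between the two parents.  Position-wise, the children's
#' XOR equals the parents' XOR, and identical parents reproduce themselves.
#'
#' @param parent_a,parent_b Equal-length 0/1 integer vectors.
#' @param k Number of cut points, `1 <= k < length(parent_a)`.
#' @return List with components `a` and `b`, the two children.
#' @export
k_point_crossover <- function(parent_a, parent_b, k) {
  L <- length(parent_a)
  stopifnot(length(parent_b) == L, k >= 1L, k < L,
            all(parent_a %in% c(0L, 1L)), all(parent_b %in% c(0L, 1L)))
  ch <- crossover_pairs(matrix(as.integer(parent_a), 1L),
                        matrix(as.integer(parent_b), 1L), as.integer(k))
  list(a = drop(ch$a), b = drop(ch$b))
}

# Per-individual mutation over a population matrix: each row is mutated
# with probability `rate` by flipping exactly one uniformly chosen bit.
mutate_pop <- function(B, rate) {
  if (rate <= 0) return(B)
  n <- nrow(B); L <- ncol(B)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    pos <- sample.int(L, length(hit), replace = TRUE)
    ij <- cbind(hit, pos)
    B[ij] <- 1L - B[ij]
  }
  B
}

#' Mutate a bit string
#'
#' With probability `rate` the chromosome is mutated by flipping exactly one
#' uniformly chosen bit; otherwise it is returned unchanged.
#'
#' @param bits 0/1 integer vector.
#' @param rate Mutation probability in `[0, 1]`.
#' @return The (possibly) mutated bit vector.
#' @export
mutate_chromosome <- function(bits, rate) {
  stopifnot(rate >= 0, rate <= 1)
  drop(mutate_pop(matrix(as.integer(bits), nrow = 1L), rate))
}

# ---- sub-populations and cooperative chromosomes ---------------------------

new_subpopulation <- function(variable_name, variable_index, bounds, n, L) {
  structure(list(variable_name = variable_name,
                 variable_index = as.integer(variable_index),
                 bounds = as.numeric(bounds),
                 bits = matrix(sample(0:1, n * L, replace = TRUE), n, L)),
            class = "sub_population")
}

subpop_values <- function(sp, gray = FALSE) {
  decode_matrix(sp$bits, sp$bounds[1], sp$bounds[2], gray = gray)
}

#' Assemble a cooperative chromosome
#'
#' Combines one chosen member from every sub-population into a complete
#' candidate solution over the tunable variables.
#'
#' @param subpops List of sub-populations (as built by [run_ncga()]'s
#'   initialization or returned in its run record).
#' @param chosen Integer vector, one member index per sub-population.
#' @param gray Decode bit strings as Gray code.
#' @return A `cooperative_chromosome`: `representatives` (one bit vector per
#'   sub-population, with its member index) and `decoded_state` (named value
#'   per tunable variable, within bounds by construction).
#' @export
assemble_cooperative <- function(subpops, chosen, gray = FALSE) {
  if (length(chosen) != length(subpops))
    stop("need exactly one chosen member per sub-population (got ",
         length(chosen), " for ", length(subpops), ")")
  reps <- vector("list", length(subpops))
  vals <- numeric(length(subpops))
  for (i in seq_along(subpops)) {
    sp <- subpops[[i]]
    bits <- sp$bits[chosen[i], ]
    reps[[i]] <- list(variable_name = sp$variable_name,
                      variable_index = sp$variable_index,
                      member = as.integer(chosen[i]), bits = bits)
    vals[i] <- decode_matrix(matrix(bits, 1L), sp$bounds[1], sp$bounds[2],
                             gray = gray)
  }
  structure(list(representatives = reps,
                 decoded_state = stats::setNames(
                   vals, vapply(subpops, `[[`, character(1), "variable_name"))),
            class = "cooperative_chromosome")
}

#' Decompose a cooperative chromosome
#'
#' Returns the per-sub-population representatives, inverting
#' [assemble_cooperative()].
#'
#' @param coop A `cooperative_chromosome`.
#' @return List with one `(variable_name, variable_index, member, bits)`
#'   entry per sub-population.
#' @export
decompose_cooperative <- function(coop) {
  stopifnot(inherits(coop, "cooperative_chromosome"))
  coop$representatives
}
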