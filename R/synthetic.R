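#' @name synthetic_data
#' @title Synthetic inputs: fixture SMILES and planted Gaussian mixtures
#'
#' @description
#' Everything the pipeline needs can be generated without a download: valid
#' drug-like SMILES assembled from a curated fragment grammar (aromatic and
#' aliphatic ring cores, alkyl chains, carboxylates, sulfonamides, amides,
#' nitro groups, aryl halides, nitriles, chiral and cis/trans motifs), and
#' feature-space Gaussian mixtures with planted cluster structure for
#' recovery tests. All generators are pure functions of their seed.
NULL

.FRAGMENT_CORES <- c(
  "c1ccccc1", "c1ccc(%s)cc1", "c1ccncc1", "c1ccc(%s)nc1",
  "c1ccoc1", "c1ccsc1", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1",
  "c1ccc2ccccc2c1")

.FRAGMENT_DECORATIONS <- c(
  "C(=O)O", "C(=O)N", "C(=O)OC", "S(=O)(=O)N", "S(=O)(=O)NC",
  "N", "NC", "N(C)C", "O", "OC", "F", "Cl", "Br", "I",
  "C#N", "[N+](=O)[O-]", "C(F)(F)F", "NC(C)=O", "C=C")

.FRAGMENT_MOTIFS <- c(
  "C[C@H](N)C(=O)O", "C[C@@H](O)c1ccccc1", "C/C=C/C(=O)O",
  "F/C=C\\F", "CC(=O)[O-]", "C[N+](C)(C)C", "OCC(O)CO",
  "N#Cc1ccc(S(=O)(=O)N)cc1", "Clc1ccc(C(=O)O)cc1")

# The three mandatory edge cases: a single heavy atom, a 2-atom/1-bond
# molecule, and the 3-atom/2-bond minimum observed in real libraries.
.EDGE_CASE_SMILES <- c("O", "CO", "CCO")

#' Generate valid fixture SMILES
#'
#' Assembles `n` molecules from the fragment grammar. The first three
#' entries are always the degenerate edge cases `O`, `CO` and `CCO`
#' (when `n >= 3`); the remainder mixes substituted ring cores, alkyl
#' chains and curated functional-group motifs. Every output re-parses.
#'
#' @param n Number of molecules (`n >= 1`).
#' @param seed Integer seed; the output is a pure function of it.
#' @return A data frame with columns `id` and `smiles`.
#' @export
#' @examples
#' head(fixture_smiles(10, seed = 1))
fixture_smiles <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  smiles <- .with_seed(seed, {
    out <- character(n)
    base <- .EDGE_CASE_SMILES[seq_len(min(n, 3L))]
    out[seq_along(base)] <- base
    i <- length(base) + 1L
    while (i <= n) {
      roll <- stats::runif(1)
      out[i] <- if (roll < 0.15) {
        # plain alkyl chain, optionally branched/terminated
        len <- sample(1:8, 1)
        term <- sample(c("", "O", "N", "C(=O)O"), 1)
        paste0(strrep("C", len), term)
      } else if (roll < 0.30) {
        sample(.FRAGMENT_MOTIFS, 1)
      } else {
        core <- sample(.FRAGMENT_CORES, 1)
        if (grepl("%s", core, fixed = TRUE)) {
          sprintf(core, sample(.FRAGMENT_DECORATIONS, 1))
        } else {
          pre <- sample(c("", "C", "CC", "CCC", "OC", "NC"), 1)
          dec <- sample(c("", sample(.FRAGMENT_DECORATIONS, 1)), 1)
          paste0(pre, core, dec)
        }
      }
      i <- i + 1L
    }
    out
  })
  data.frame(id = sprintf("FIX%05d", seq_len(n)), smiles = smiles,
             stringsAsFactors = FALSE)
}

#' Specification for a planted Gaussian mixture
#'
#' @param n Total number of points.
#' @param dim Dimensionality.
#' @param k_true Number of planted clusters (`n >= k_true >= 1`).
#' @param separation Minimum pairwise centroid distance, in units of the
#'   (unit) within-cluster standard deviation. `separation >= 0`.
#' @param seed Integer seed.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n, dim, k_true, separation, seed = 1L) {
  stopifnot(n >= k_true, k_true >= 1L, separation >= 0, dim >= 1L)
  structure(list(n = as.integer(n), dim = as.integer(dim),
                 k_true = as.integer(k_true), separation = separation,
                 seed = as.integer(seed)), class = "mixture_spec")
}

#' Sample a planted Gaussian mixture
#'
#' Draws `k_true` isotropic Gaussian blobs with unit within-cluster SD and
#' centroids at pairwise distance at least `separation`: centroid
#' directions are drawn isotropically at random and the configuration is
#' rescaled so its *minimum* pairwise distance equals `separation` (the
#' stated spacing is attained by the closest pair; most pairs are farther
#' apart, as in a randomly planted mixture). Cluster sizes are balanced
#' within one point. An error is raised in the degenerate case where
#' distinct centroids cannot be drawn.
#'
#' @param spec A `mixture_spec`.
#' @return List with `X` (n x dim matrix), `labels` (integers `0 .. k-1`,
#'   for external validation in tests) and `spec`.
#' @export
gaussian_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  n <- spec$n; dim <- spec$dim; k <- spec$k_true; sep <- spec$separation
  .with_seed(spec$seed, {
    if (sep == 0 || k == 1L) {
      centers <- matrix(0, k, dim)
    } else {
      centers <- matrix(stats::rnorm(k * dim), k, dim)
      dmin <- min(stats::dist(centers))
      tries <- 0L
      while (dmin < 1e-8) {  # essentially impossible for continuous draws
        centers <- matrix(stats::rnorm(k * dim), k, dim)
        dmin <- min(stats::dist(centers))
        tries <- tries + 1L
        if (tries > 100L) {
          stop("cannot place ", k, " distinct centroids at separation ", sep,
               " in ", dim, " dimensions", call. = FALSE)
        }
      }
      centers <- centers * (sep / dmin)
    }
    labels <- rep(seq_len(k), length.out = n)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * dim), n, dim)
    list(X = X, labels = labels - 1L, spec = spec)
  })
}
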