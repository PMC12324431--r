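#' @useDynLib minscfg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance augment
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

#' The six canonical RNA base pairs
#'
#' Watson-Crick-Franklin A:U and G:C pairs plus the G:U wobble pair, in
#' both orientations.
#'
#' @return A two-column character matrix with one canonical ordered pair
#'   per row.
#' @export
canonical_pairs <- function() {
  m <- matrix(c("A", "U", "U", "A", "C", "G", "G", "C", "G", "U", "U", "G"),
              ncol = 2, byrow = TRUE)
  colnames(m) <- c("first", "second")
  m
}

new_ps <- function(x) {
  x <- as.numeric(x)
  names(x) <- RNA_ALPHABET
  x
}

new_pbp <- function(x) {
  m <- matrix(as.numeric(x), 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  m
}

#' Construct G6 grammar parameters
#'
#' The G6 grammar has nonterminals S, L and F with rules
#' `S -> LS | L`, `L -> aFb | a`, `F -> aFb | LS`.  Its parameterization
#' consists of three Bernoulli probabilities — `tS` (chain continuation),
#' `tL` (helix initiation) and `tF` (helix extension) — plus a single-
#' nucleotide emission simplex `ps` over A,C,G,U and a 16-cell ordered
#' base-pair emission simplex `pbp`.  That gives 3 + 3 + 15 = 21 free
#' parameters.
#'
#' @param tS,tL,tF Bernoulli rule probabilities in `[0, 1]`.
#' @param ps Numeric vector of 4 single-nucleotide emission probabilities
#'   in A,C,G,U order; must sum to 1.
#' @param pbp Numeric 4x4 matrix (or length-16 row-major vector) of
#'   ordered pair emission probabilities; must sum to 1.  The table is
#'   not symmetrized: `pbp["G","C"]` and `pbp["C","G"]` are distinct.
#' @return An object of class `c("g6_params", "scfg_params")`.
#' @seealso [g5_params()], [uniform_params()], [random_params()]
#' @export
g6_params <- function(tS, tL, tF, ps, pbp) {
  p <- structure(
    list(grammar = "G6", tS = as.numeric(tS), tL = as.numeric(tL),
         tF = as.numeric(tF), ps = new_ps(ps), pbp = new_pbp(pbp)),
    class = c("g6_params", "scfg_params"))
  validate_params(p)
  p
}

#' Construct G5 grammar parameters
#'
#' The G5 grammar has a single nonterminal with rules
#' `S -> aS | aSbS | eps`, carrying probabilities `tu`, `tp` and
#' `1 - tu - tp` respectively, plus the same `ps` and `pbp` emission
#' simplices as G6: 2 + 3 + 15 = 20 free parameters.  Unlike G6, G5 has
#' a single pairing probability, so it cannot favour helices over
#' isolated base pairs.
#'
#' @param tu Probability of emitting an unpaired residue.
#' @param tp Probability of emitting a base pair; `tu + tp` must be at
#'   most 1.
#' @inheritParams g6_params
#' @return An object of class `c("g5_params", "scfg_params")`.
#' @export
g5_params <- function(tu, tp, ps, pbp) {
  p <- structure(
    list(grammar = "G5", tu = as.numeric(tu), tp = as.numeric(tp),
         ps = new_ps(ps), pbp = new_pbp(pbp)),
    class = c("g5_params", "scfg_params"))
  validate_params(p)
  p
}

check_grammar <- function(grammar) {
  grammar <- toupper(as.character(grammar)[1])
  if (!grammar %in% c("G6", "G5"))
    abort(paste0("unknown grammar '", grammar, "'; expected \"G6\" or \"G5\""))
  grammar
}

#' Validate an SCFG parameter object
#'
#' Checks the simplex and range invariants: Bernoullis in `[0, 1]`
#' (for G5, `tu + tp <= 1`), `ps` and `pbp` nonnegative and summing to 1
#' within `tol`.
#'
#' @param params An `scfg_params` object.
#' @param tol Tolerance for simplex sums (default `1e-9`).
#' @return `params`, invisibly; errors if an invariant is violated.
#' @export
validate_params <- function(params, tol = 1e-9) {
  if (!inherits(params, "scfg_params"))
    abort("`params` must be an scfg_params object")
  if (identical(params$grammar, "G6")) {
    for (nm in c("tS", "tL", "tF")) {
      v <- params[[nm]]
      if (!is.finite(v) || v < 0 || v > 1)
        abort(paste0("`", nm, "` must lie in [0, 1], got ", v))
    }
  } else {
    if (!is.finite(params$tu) || params$tu < 0 ||
        !is.finite(params$tp) || params$tp < 0 ||
        params$tu + params$tp > 1 + tol)
      abort("`tu`, `tp` must be nonnegative with tu + tp <= 1")
  }
  if (any(params$ps < 0) || abs(sum(params$ps) - 1) > tol)
    abort("`ps` must be a probability vector over A,C,G,U summing to 1")
  if (any(params$pbp < 0) || abs(sum(params$pbp) - 1) > tol)
    abort("`pbp` must be a 16-cell probability table summing to 1")
  invisible(params)
}

#' Number of free parameters of a grammar
#'
#' Counts independent parameters after the simplex and Bernoulli
#' constraints: G6 has 3 (Bernoullis) + 3 (ps) + 15 (pbp) = 21; G5 has
#' 2 + 3 + 15 = 20.
#'
#' @param grammar `"G6"` or `"G5"`, or an `scfg_params` object.
#' @return An integer count.
#' @export
count_free_parameters <- function(grammar) {
  if (inherits(grammar, "scfg_params")) grammar <- grammar$grammar
  grammar <- check_grammar(grammar)
  if (grammar == "G6") 3L + 3L + 15L else 2L + 3L + 15L
}

#' Maximum-entropy (uniform) initialization
#'
#' Every rule distribution is set to the discrete uniform: all G6
#' Bernoullis 0.5 (G5: `tu = tp = 1/3`), `ps(a) = 1/4`,
#' `pbp(a,b) = 1/16`.
#'
#' @param grammar `"G6"` or `"G5"`.
#' @return An `scfg_params` object.
#' @export
uniform_params <- function(grammar = "G6") {
  grammar <- check_grammar(grammar)
  ps <- rep(0.25, 4)
  pbp <- matrix(1 / 16, 4, 4)
  if (grammar == "G6") g6_params(0.5, 0.5, 0.5, ps, pbp)
  else g5_params(1 / 3, 1 / 3, ps, pbp)
}

rsimplex <- function(k) {
  # flat (Dirichlet(1,...,1)) draw on the k-simplex
  g <- stats::rexp(k)
  g / sum(g)
}

#' Random initialization
#'
#' Each rule distribution is drawn from a flat (Dirichlet with unit
#' concentration) distribution on its simplex.  Deterministic given
#' `seed`.
#'
#' @param grammar `"G6"` or `"G5"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `scfg_params` object.
#' @export
random_params <- function(grammar = "G6", seed = NULL) {
  grammar <- check_grammar(grammar)
  draw <- function() {
    ps <- rsimplex(4)
    pbp <- matrix(rsimplex(16), 4, 4)
    if (grammar == "G6") {
      b <- stats::runif(3)
      g6_params(b[1], b[2], b[3], ps, pbp)
    } else {
      t3 <- rsimplex(3)
      g5_params(t3[1], t3[2], ps, pbp)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

PROB_FLOOR <- 1e-30

#' Renormalize SCFG parameters
#'
#' Rescales each Bernoulli pair (G5: the rule triple) and each emission
#' table to sum to 1.  Raw entries are floored at `1e-30` before
#' normalization so that log-space arithmetic never produces `-Inf`
#' during training.  Idempotent on already-valid parameters.
#'
#' @param params An `scfg_params`-shaped list; entries need not sum to 1
#'   but must be finite and nonnegative.
#' @return A valid `scfg_params` object.
#' @export
normalize_params <- function(params) {
  norm1 <- function(x, what) {
    x <- pmax(as.numeric(x), PROB_FLOOR)
    if (!all(is.finite(x)) || sum(x) <= 0)
      abort(paste0("cannot normalize `", what, "`: entries must be finite and not all zero"))
    x / sum(x)
  }
  # Bernoullis stored as p alone: cap below 1 - 1e-12 so that 1 - p
  # stays representable in double precision (p = 1 - 1e-30 would round
  # to exactly 1 and make log(1 - p) = -Inf)
  cap <- function(p) min(p, 1 - 1e-12)
  if (identical(params$grammar, "G6")) {
    bS <- norm1(c(params$tS, 1 - params$tS), "tS")
    bL <- norm1(c(params$tL, 1 - params$tL), "tL")
    bF <- norm1(c(params$tF, 1 - params$tF), "tF")
    g6_params(cap(bS[1]), cap(bL[1]), cap(bF[1]), norm1(params$ps, "ps"),
              matrix(norm1(params$pbp, "pbp"), 4, 4))
  } else {
    t3 <- norm1(c(params$tu, params$tp, 1 - params$tu - params$tp), "tu/tp")
    g5_params(t3[1], t3[2], norm1(params$ps, "ps"),
              matrix(norm1(params$pbp, "pbp"), 4, 4))
  }
}

#' @export
print.scfg_params <- function(x, digits = 4, ...) {
  cat("<scfg_params> grammar", x$grammar,
      sprintf("(%d free parameters)\n", count_free_parameters(x)))
  if (x$grammar == "G6") {
    cat(sprintf("  tS = %.*f  tL = %.*f  tF = %.*f\n",
                digits, x$tS, digits, x$tL, digits, x$tF))
  } else {
    cat(sprintf("  tu = %.*f  tp = %.*f  (eps = %.*f)\n",
                digits, x$tu, digits, x$tp, digits, 1 - x$tu - x$tp))
  }
  cat("  ps :", paste(sprintf("%s %.*f", names(x$ps), digits, x$ps),
                      collapse = "  "), "\n")
  cat(sprintf("  pbp: %.*f of mass on the 6 canonical pairs\n",
              digits, canonical_pbp_mass(x)))
  invisible(x)
}

#' Probability mass on the six canonical base pairs
#'
#' Sums `pbp` over the ordered pairs A:U, U:A, C:G, G:C, G:U, U:G — the
#' Watson-Crick-Franklin pairs plus wobble.  A grammar that has learned
#' RNA base-pairing rules concentrates most of its pair-emission mass
#' here.
#'
#' @param params An `scfg_params` object.
#' @return A number in `[0, 1]`.
#' @export
canonical_pbp_mass <- function(params) {
  cp <- canonical_pairs()
  sum(params$pbp[cp])
}

#' @rdname tidy.scfg_fit
#' @method tidy scfg_params
#' @export
tidy.scfg_params <- function(x, ...) {
  bern <- if (x$grammar == "G6") {
    tibble(component = "transition",
           term = c("tS", "tL", "tF"),
           estimate = c(x$tS, x$tL, x$tF))
  } else {
    tibble(component = "transition",
           term = c("tu", "tp", "eps"),
           estimate = c(x$tu, x$tp, 1 - x$tu - x$tp))
  }
  ps <- tibble(component = "ps", term = names(x$ps), estimate = unname(x$ps))
  idx <- expand.grid(a = RNA_ALPHABET, b = RNA_ALPHABET,
                     stringsAsFactors = FALSE)
  pbp <- tibble(component = "pbp",
                term = paste0(idx$a, ":", idx$b),
                estimate = as.vector(x$pbp[cbind(idx$a, idx$b)]))
  dplyr::bind_rows(bern, ps, pbp)
}

# ------------------------------------------------------- parameter files --

#' Read and write SCFG parameter files
#'
#' Parameters are stored as plain-text YAML with fields `grammar`,
#' the transition probabilities (`tS`/`tL`/`tF` for G6, `tu`/`tp` for
#' G5), `ps` (4 values in A,C,G,U order) and `pbp` (16 values,
#' row-major over A,C,G,U x A,C,G,U).  Values are written with 15
#' significant digits so a write/read round trip reproduces the
#' parameters to within double-precision rounding.
#'
#' @param params An `scfg_params` object.
#' @param path File path.
#' @return `read_params()` returns an `scfg_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- list(grammar = params$grammar)
  if (params$grammar == "G6") {
    x$tS <- params$tS; x$tL <- params$tL; x$tF <- params$tF
  } else {
    x$tu <- params$tu; x$tp <- params$tp
  }
  x$ps <- unname(params$ps)
  x$pbp <- as.vector(t(params$pbp))  # row-major
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  x <- yaml::read_yaml(path)
  grammar <- check_grammar(x$grammar)
  if (length(x$ps) != 4) abort("`ps` must have 4 entries (A,C,G,U order)")
  if (length(x$pbp) != 16) abort("`pbp` must have 16 entries (row-major)")
  pbp <- matrix(as.numeric(x$pbp), 4, 4, byrow = TRUE)
  if (grammar == "G6") g6_params(x$tS, x$tL, x$tF, x$ps, pbp)
  else g5_params(x$tu, x$tp, x$ps, pbp)
}
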