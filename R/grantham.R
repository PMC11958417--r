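#' Grantham amino-acid distance model
#'
#' Builds the 20x20 Grantham distance matrix from the published residue
#' properties (composition `c`, polarity `p`, molecular volume `v`) and
#' weights:
#' \deqn{D_{ij} = \rho \sqrt{\alpha (c_i - c_j)^2 + \beta (p_i - p_j)^2 +
#'   \gamma (v_i - v_j)^2}}
#' By default the scale factor `rho` is calibrated so that the mean of the 190
#' inter-residue distances is 100, the convention under which the published
#' integer matrix was tabulated (giving e.g. D(L,I) = 5 and D(C,W) = 215, the
#' matrix minimum and maximum).
#'
#' @param alpha,beta,gamma Property weights.
#' @param rho Scale factor; `NULL` (default) calibrates the mean to 100.
#' @param round_matrix Round distances to integers as in the published table.
#' @return Object of class `grantham_model`: list with `properties` (data.frame
#'   of c/p/v per residue), the weights, `rho`, and `matrix` (20x20, residue
#'   one-letter codes as dimnames).
#' @export
grantham_model <- function(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                           rho = NULL, round_matrix = TRUE) {
  aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  comp <- c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
            0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13)
  pol  <- c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
            6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4)
  vol  <- c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
            136, 55, 96, 85, 56, 119, 54, 83, 105, 170)
  names(comp) <- names(pol) <- names(vol) <- aa
  raw <- outer(seq_along(aa), seq_along(aa), function(i, j) {
    sqrt(alpha * (comp[i] - comp[j])^2 +
         beta  * (pol[i]  - pol[j])^2 +
         gamma * (vol[i]  - vol[j])^2)
  })
  dimnames(raw) <- list(aa, aa)
  if (is.null(rho)) rho <- 100 / mean(raw[upper.tri(raw)])
  m <- rho * raw
  if (round_matrix) m <- round(m)
  structure(list(
    properties = data.frame(residue = aa, c = comp, p = pol, v = vol,
                            row.names = aa),
    alpha = alpha, beta = beta, gamma = gamma, rho = rho, matrix = m),
    class = "grantham_model")
}

.mhcseg_env <- new.env(parent = emptyenv())

default_grantham <- function() {
  if (is.null(.mhcseg_env$grantham))
    .mhcseg_env$grantham <- grantham_model()
  .mhcseg_env$grantham
}

#' Grantham distance between two residues
#'
#' @param res1,res2 One-letter amino-acid codes.
#' @param model A [grantham_model()]; the cached default if omitted.
#' @param nonstandard `"error"` (default) or `"na"` for residues outside the
#'   20 standard amino acids (e.g. `X`, gaps).
#' @return Numeric distance (0 for identical residues).
#' @export
grantham_pair <- function(res1, res2, model = default_grantham(),
                          nonstandard = c("error", "na")) {
  nonstandard <- match.arg(nonstandard)
  r1 <- toupper(res1); r2 <- toupper(res2)
  ok <- r1 %in% rownames(model$matrix) & r2 %in% rownames(model$matrix)
  if (!all(ok)) {
    if (nonstandard == "error")
      stop("nonstandard residue(s): ",
           paste(unique(c(r1, r2)[!c(ok, ok)]), collapse = ", "))
    out <- rep(NA_real_, length(r1))
    out[ok] <- model$matrix[cbind(r1[ok], r2[ok])]
    return(out)
  }
  unname(model$matrix[cbind(r1, r2)])
}

#' Mean per-site Grantham distance between two aligned proteins
#'
#' Averages [grantham_pair()] over compared sites; columns where either
#' sequence has a gap or a nonstandard residue are excluded (pairwise
#' deletion). `mode = "sum"` returns the unaveraged site total.
#'
#' @param aa1,aa2 Aligned amino-acid strings of equal length.
#' @param model A [grantham_model()].
#' @param mode `"mean"` (default, Grantham units per compared site) or `"sum"`.
#' @param sites Optional integer vector of 1-based alignment columns to
#'   restrict the comparison to (e.g. peptide-binding-region positions).
#' @return Non-negative numeric scalar.
#' @export
functional_distance <- function(aa1, aa2, model = default_grantham(),
                                mode = c("mean", "sum"), sites = NULL) {
  mode <- match.arg(mode)
  if (nchar(aa1) != nchar(aa2)) stop("sequences must be aligned (equal length)")
  a <- strsplit(toupper(aa1), "")[[1]]
  b <- strsplit(toupper(aa2), "")[[1]]
  if (!is.null(sites)) {
    stopifnot(all(sites >= 1 & sites <= length(a)))
    a <- a[sites]; b <- b[sites]
  }
  std <- rownames(model$matrix)
  use <- a %in% std & b %in% std
  if (!any(use)) stop("no comparable sites between sequences")
  d <- model$matrix[cbind(a[use], b[use])]
  if (mode == "mean") mean(d) else sum(d)
}
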