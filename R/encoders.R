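# Feature encoders: nucleotide chemical properties (NCP), composition of
# k-spaced nucleic acid pairs (CKSNAP), and Type-I pseudo k-tuple
# nucleotide composition (PseKNC).

#' The nucleotide chemical property (NCP) code
#'
#' Three binary flags per nucleotide: ring class (purine = 1,
#' pyrimidine = 0), functional group (amino = 1, keto = 0), and
#' hydrogen bonding (weak = 1, strong = 0), giving A = (1,1,1),
#' C = (0,1,0), G = (1,0,0), U = (0,0,1). No two nucleotides share more
#' than one property class, so every pair of codes differs in exactly
#' two flags. `N` (pad/ambiguous) maps to (0,0,0).
#'
#' @return a 5x3 numeric matrix, rows A/C/G/U/N, columns
#'   `ring`, `func`, `hbond`.
#' @export
ncp_code <- function() {
  matrix(c(1, 1, 1,
           0, 1, 0,
           1, 0, 0,
           0, 0, 1,
           0, 0, 0),
         nrow = 5, byrow = TRUE,
         dimnames = list(c("A", "C", "G", "U", "N"),
                         c("ring", "func", "hbond")))
}

frag_residues <- function(fragment) {
  if (inherits(fragment, "fragment_dataset")) {
    if (length(fragment) != 1L) stop("expected a single fragment")
    fragment <- fragment$residues
  }
  toupper(as.character(fragment))
}

#' Encode a fragment with nucleotide chemical properties
#'
#' Position `i` (0-based) of the fragment occupies feature slots `3i`,
#' `3i+1`, `3i+2` (0-based, matching the published feature numbering)
#' in the order ring, functional group, hydrogen bond. A 21-nt fragment
#' yields 63 features; a 31-nt fragment yields 93.
#'
#' @param fragment a residue string (or single-fragment dataset).
#' @return named numeric vector of length `3 * nchar(fragment)`; names
#'   are `p<position>_<ring|func|hbond>` with 0-based positions.
#' @examples
#' encode_ncp("GAU")  # 1,0,0, 1,1,1, 0,0,1
#' @export
encode_ncp <- function(fragment) {
  residues <- frag_residues(fragment)
  chars <- strsplit(residues, "")[[1]]
  code <- ncp_code()
  bad <- which(!chars %in% rownames(code))
  if (length(bad) > 0) {
    stop(sprintf("cannot NCP-encode character '%s' at position %d (0-based %d)",
                 chars[bad[1]], bad[1], bad[1] - 1L))
  }
  v <- as.vector(t(code[chars, , drop = FALSE]))
  names(v) <- ncp_feature_names(length(chars))
  v
}

ncp_feature_names <- function(n) {
  as.vector(t(outer(seq_len(n) - 1L, c("ring", "func", "hbond"),
                    function(p, prop) paste0("p", p, "_", prop))))
}

#' Encode a fragment with k-spaced nucleotide pair composition (CKSNAP)
#'
#' For each gap `g` in `0..k_max` and each ordered nucleotide pair
#' `(x, y)`, the feature is the number of positions `i` carrying `x` at
#' `i` and `y` at `i + g + 1`, divided by the number of such positions,
#' `n - g - 1`. Pairs are ordered lexicographically (A, C, G, U) within
#' each gap block; gap blocks ascend. Pairs containing `N` are excluded
#' from the counts (the denominator is unchanged).
#'
#' @param fragment a residue string (or single-fragment dataset).
#' @param k_max largest gap (default 5, giving 96 features).
#' @return named numeric vector of length `16 * (k_max + 1)`; names are
#'   `g<gap>_<xy>`.
#' @export
encode_cksnap <- function(fragment, k_max = 5L) {
  residues <- frag_residues(fragment)
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  if (n <= k_max + 1L) {
    stop("fragment length ", n, " too short for gap ", k_max,
         " (requires length > k_max + 1)")
  }
  pairs <- as.vector(t(outer(RNA_ALPHABET, RNA_ALPHABET, paste0)))
  out <- numeric(0)
  for (g in 0:k_max) {
    i <- seq_len(n - g - 1L)
    observed <- paste0(chars[i], chars[i + g + 1L])
    counts <- table(factor(observed, levels = pairs))
    block <- as.numeric(counts) / (n - g - 1L)
    names(block) <- paste0("g", g, "_", pairs)
    out <- c(out, block)
  }
  out
}

#' RNA dinucleotide physicochemical property table
#'
#' Six rigid-body base-step parameters for the 16 RNA dinucleotides
#' (shift, slide, rise in angstroms; tilt, roll, twist in degrees),
#' the A-form duplex values commonly used for sequence-order
#' correlation features. The table obeys reverse-complement symmetry.
#'
#' @param standardize scale each property to zero mean, unit variance
#'   across the 16 dinucleotides (population SD), the form consumed by
#'   [encode_pseknc()].
#' @return 16x6 numeric matrix, rows the dinucleotides in
#'   lexicographic order.
#' @export
rna_dinucleotide_properties <- function(standardize = TRUE) {
  tab <- matrix(c(
    # shift  slide  rise   tilt  roll  twist
    -0.08, -1.27, 3.18, -0.8,  7.0, 31,   # AA
     0.23, -1.43, 3.24,  0.8,  4.8, 32,   # AC
    -0.04, -1.50, 3.30,  0.5,  8.5, 30,   # AG
    -0.06, -1.36, 3.24,  1.1,  7.1, 33,   # AU
     0.11, -1.46, 3.09,  1.0,  9.9, 31,   # CA
    -0.01, -1.78, 3.32,  0.3,  8.7, 32,   # CC
     0.30, -1.89, 3.30, -0.1, 12.1, 27,   # CG
    -0.04, -1.50, 3.30,  0.5,  8.5, 30,   # CU
     0.07, -1.70, 3.38,  1.3,  9.4, 32,   # GA
     0.07, -1.39, 3.22,  0.0,  6.1, 35,   # GC
    -0.01, -1.78, 3.32,  0.3,  8.7, 32,   # GG
     0.23, -1.43, 3.24,  0.8,  4.8, 32,   # GU
    -0.02, -1.45, 3.26, -0.2, 10.7, 32,   # UA
     0.07, -1.70, 3.38,  1.3,  9.4, 32,   # UC
     0.11, -1.46, 3.09,  1.0,  9.9, 31,   # UG
    -0.08, -1.27, 3.18, -0.8,  7.0, 31),  # UU
    nrow = 16, byrow = TRUE,
    dimnames = list(as.vector(t(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))),
                    c("shift", "slide", "rise", "tilt", "roll", "twist")))
  if (standardize) {
    tab <- apply(tab, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  }
  tab
}

#' Encode a fragment with Type-I pseudo k-tuple composition (PseKNC)
#'
#' The first `4^k` entries are the normalized k-tuple frequencies
#' damped by the weighted sequence-order factors; the last `lambda`
#' entries are the weighted tier-j correlation factors
#' `theta_j` — the mean, over all dinucleotide pairs `j` apart, of the
#' mean squared difference of their standardized property values. The
#' whole vector sums to 1. Tuples or dinucleotide pairs containing `N`
#' are skipped.
#'
#' @param fragment a residue string (or single-fragment dataset).
#' @param k tuple size (default 2).
#' @param lambda number of correlation tiers (default 2); must be
#'   smaller than `nchar(fragment) - 1`.
#' @param w correlation weight in `[0, 1]` (default 0.5); `w = 0`
#'   reduces the first block to plain k-tuple composition.
#' @param property_table standardized 16x6 dinucleotide property
#'   matrix; defaults to [rna_dinucleotide_properties()].
#' @return named numeric vector of length `4^k + lambda`.
#' @export
encode_pseknc <- function(fragment, k = 2L, lambda = 2L, w = 0.5,
                          property_table = rna_dinucleotide_properties()) {
  residues <- frag_residues(fragment)
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  if (lambda >= n - 1L) stop("lambda must be < fragment length - 1 (got lambda=",
                             lambda, ", length=", n, ")")
  if (w < 0 || w > 1) stop("w must lie in [0,1]")
  tuples <- apply(expand.grid(rep(list(RNA_ALPHABET), k))[, k:1, drop = FALSE],
                  1, paste, collapse = "")
  starts <- seq_len(n - k + 1L)
  obs <- vapply(starts, function(i) paste(chars[i:(i + k - 1L)], collapse = ""), character(1))
  obs <- obs[!grepl("N", obs)]
  counts <- table(factor(obs, levels = tuples))
  f <- as.numeric(counts)
  if (sum(f) == 0) stop("no valid k-tuples in fragment (all contain N)")
  f <- f / sum(f)
  theta <- vapply(seq_len(lambda), function(j) {
    i <- seq_len(n - 1L - j)
    d1 <- paste0(chars[i], chars[i + 1L])
    d2 <- paste0(chars[i + j], chars[i + j + 1L])
    ok <- !grepl("N", d1) & !grepl("N", d2)
    if (!any(ok)) return(0)
    mean(vapply(which(ok), function(m) {
      mean((property_table[d1[m], ] - property_table[d2[m], ])^2)
    }, numeric(1)))
  }, numeric(1))
  denom <- 1 + w * sum(theta)
  v <- c(f / denom, w * theta / denom)
  names(v) <- c(paste0("k", k, "_", tuples), paste0("theta", seq_len(lambda)))
  v
}

#' Encode every fragment of a dataset into a feature matrix
#'
#' Row `i` corresponds to fragment `i`; labels are carried alongside
#' (as attributes), never inside the matrix.
#'
#' @param dataset a `fragment_dataset`.
#' @param encoder `"NCP"`, `"CKSNAP"`, or `"PseKNC"`.
#' @param ... encoder parameters (`k_max`; `k`, `lambda`, `w`,
#'   `property_table`).
#' @return a numeric matrix of class `psi_features` with feature names
#'   as column names, fragment ids as row names, and attributes
#'   `encoder_id`, `encoder_params`, `label`, `window_length`.
#' @export
encode_dataset <- function(dataset, encoder = c("NCP", "CKSNAP", "PseKNC"), ...) {
  encoder <- match.arg(encoder)
  params <- list(...)
  fun <- switch(encoder,
                NCP = encode_ncp,
                CKSNAP = encode_cksnap,
                PseKNC = encode_pseknc)
  n <- length(dataset)
  if (n == 0L) {
    w <- dataset$window_length
    if (is.na(w)) stop("cannot encode an empty dataset without a declared window_length")
    template <- do.call(fun, c(list(strrep("A", (w - 1L) %/% 2L) %+%
                                      "U" %+% strrep("A", (w - 1L) %/% 2L)), params))
    m <- matrix(numeric(0), nrow = 0, ncol = length(template),
                dimnames = list(NULL, names(template)))
  } else {
    rows <- lapply(seq_len(n), function(i) {
      tryCatch(do.call(fun, c(list(dataset$residues[i]), params)),
               error = function(e) stop("fragment '", dataset$id[i], "': ",
                                        conditionMessage(e), call. = FALSE))
    })
    m <- do.call(rbind, rows)
    rownames(m) <- dataset$id
  }
  structure(m, class = c("psi_features", class(m)),
            encoder_id = encoder, encoder_params = params,
            label = dataset$label, window_length = dataset$window_length)
}

`%+%` <- function(a, b) paste0(a, b)

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path; the `<path>.json` sidecar restores the encoder
#'   identity and parameters.
#' @return a `psi_features` matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(m) <- df$id
  lab <- df$label
  lab[lab == "" | lab == "NA"] <- NA_character_
  structure(m, class = c("psi_features", class(m)),
            encoder_id = meta$encoder_id,
            encoder_params = as.list(meta$encoder_params),
            label = lab, window_length = meta$window_length)
}

#' Write a feature matrix as TSV with a JSON parameter sidecar
#'
#' @param fm a `psi_features` matrix from [encode_dataset()].
#' @param path output TSV path; the sidecar is written to
#'   `<path>.json`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm) %||% seq_len(nrow(fm)),
                   label = attr(fm, "label"),
                   unclass(fm)[, , drop = FALSE], check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(encoder_id = attr(fm, "encoder_id"),
         encoder_params = attr(fm, "encoder_params"),
         n_samples = nrow(fm), n_features = ncol(fm),
         window_length = attr(fm, "window_length")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
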