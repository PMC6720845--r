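# Feature assembly: subcellular-location encoding, correlation-based feature
# selection, min-max (mapminmax-style) normalization, and the 20-dimensional
# domain-pair vectors fed to the SVM.

#' The ten subcellular-location categories and their integer codes
#' @return named integer vector (Nuclear = 1 ... Vacuolar = 10)
#' @export
location_codes <- function() {
  c("Nuclear" = 1L, "Plasma membrane" = 2L, "Extracellular" = 3L,
    "Cytoplasmic" = 4L, "Mitochondrial" = 5L, "Endoplasmic reticulum" = 6L,
    "Peroxisomal" = 7L, "Lysosomal" = 8L, "Golgi" = 9L, "Vacuolar" = 10L)
}

#' Encode a subcellular-location name as its integer code
#'
#' @param location_name location category name, case-insensitive
#' @return integer code 1-10 (vectorized)
#' @export
encode_location <- function(location_name) {
  codes <- location_codes()
  idx <- match(tolower(location_name), tolower(names(codes)))
  if (anyNA(idx))
    stop("unknown location '", location_name[which(is.na(idx))[1L]],
         "'; valid categories: ", paste(names(codes), collapse = ", "))
  unname(codes[idx])
}

#' The model's ten per-domain features, in their fixed order
#' @export
paper_feature_order <- function() {
  c("n_residues", "theoretical_pi", "n_negative", "n_positive", "n_atoms",
    "ext_coefficient_1", "instability_index", "aliphatic_index", "gravy",
    "location_code")
}

#' Greedy correlation filter over candidate feature columns
#'
#' For every column pair with `|Pearson r| > threshold` (strict), the
#' later column in the declared order is dropped; earlier columns win.
#'
#' @param feature_matrix numeric matrix, candidate features in columns
#' @param threshold correlation cutoff in (0, 1]; 1 retains everything
#' @return integer indices of the retained columns
#' @export
correlation_filter <- function(feature_matrix, threshold = 0.8) {
  feature_matrix <- as.matrix(feature_matrix)
  p <- ncol(feature_matrix)
  sds <- apply(feature_matrix, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant column(s) ", paste(which(sds == 0), collapse = ", "),
            ": correlations treated as 0")
  r <- suppressWarnings(stats::cor(feature_matrix))
  r[!is.finite(r)] <- 0
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(p) > j)
    drop <- later[abs(r[j, later]) > threshold]
    keep[drop] <- FALSE
  }
  which(keep)
}

#' Fit a min-max normalizer on a training matrix
#'
#' Learns per-feature `x_min`/`x_max` mapping each training column linearly
#' onto `[y_min, y_max]` (the mapminmax transform
#' `y = (y_max - y_min) * (x - x_min)/(x_max - x_min) + y_min`).
#' Parameters are learned once on training data and reused unchanged on
#' evaluation data.
#'
#' @param training_matrix numeric matrix (>= 2 rows), features in columns
#' @param y_min,y_max target range, default (-1, 1)
#' @return object of class `minmax_normalizer`
#' @export
fit_normalizer <- function(training_matrix, y_min = -1, y_max = 1) {
  m <- as.matrix(training_matrix)
  if (nrow(m) < 2L) stop("need at least 2 training rows")
  if (y_max <= y_min) stop("y_max must exceed y_min")
  x_min <- apply(m, 2L, min)
  x_max <- apply(m, 2L, max)
  if (any(x_max == x_min))
    warning("degenerate feature(s) ",
            paste(which(x_max == x_min), collapse = ", "),
            " (x_min == x_max): mapped to the range midpoint")
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Values outside the training range are clipped to `[y_min, y_max]` rather
#' than extrapolated, keeping the SVM input domain bounded.
#'
#' @param params a `minmax_normalizer` from [fit_normalizer()]
#' @param matrix numeric matrix with the same column count as the training set
#' @return normalized matrix
#' @export
apply_normalizer <- function(params, matrix) {
  stopifnot(inherits(params, "minmax_normalizer"))
  m <- as.matrix(matrix)
  if (ncol(m) != length(params$x_min))
    stop("column count ", ncol(m), " does not match the ",
         length(params$x_min), " features the normalizer was fitted on")
  out <- m
  for (j in seq_len(ncol(m))) {
    rng <- params$x_max[j] - params$x_min[j]
    if (rng == 0) {
      out[, j] <- (params$y_min + params$y_max) / 2
    } else {
      y <- (params$y_max - params$y_min) * (m[, j] - params$x_min[j]) / rng +
        params$y_min
      out[, j] <- pmin(pmax(y, params$y_min), params$y_max)
    }
  }
  out
}

#' Per-domain raw (unnormalized) feature matrix in the model's feature order
#'
#' @param profiles data frame from [profile_table()]
#' @param locations data frame with columns `domain_id`, `location` (names) or
#'   `location_code`
#' @return numeric matrix, rownames = domain ids, 10 columns
#' @export
domain_feature_matrix <- function(profiles, locations) {
  loc_code <- if ("location_code" %in% names(locations)) {
    locations$location_code
  } else {
    encode_location(locations$location)
  }
  idx <- match(profiles$domain_id, locations$domain_id)
  if (anyNA(idx))
    stop("no location annotation for domain '",
         profiles$domain_id[which(is.na(idx))[1L]], "'")
  feats <- paper_feature_order()
  m <- as.matrix(profiles[, setdiff(feats, "location_code")])
  m <- cbind(m, location_code = loc_code[idx])
  rownames(m) <- profiles$domain_id
  storage.mode(m) <- "double"
  m[, feats, drop = FALSE]
}

#' Build normalized 20-dimensional domain-pair vectors
#'
#' Concatenates the normalized 10-feature vectors of the two domains of each
#' pair, first-listed domain first.
#'
#' @param feature_matrix per-domain raw feature matrix from
#'   [domain_feature_matrix()]
#' @param pairs data frame with columns `id_a`, `id_b` and optionally `label`
#'   (0/1)
#' @param params a fitted `minmax_normalizer` over the 10 per-domain features,
#'   or `NULL` to return raw (unnormalized) vectors, e.g. for fold-wise
#'   normalization inside [cross_validate()]
#' @return list with `vectors` (n x 20 matrix), `labels` (or NULL), `pairs`
#' @export
build_pair_vectors <- function(feature_matrix, pairs, params) {
  miss <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(feature_matrix))
  if (length(miss))
    stop("no profile for domain(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  norm <- if (is.null(params)) {
    as.matrix(feature_matrix)
  } else {
    apply_normalizer(params, feature_matrix)
  }
  rownames(norm) <- rownames(feature_matrix)
  v <- cbind(norm[pairs$id_a, , drop = FALSE], norm[pairs$id_b, , drop = FALSE])
  colnames(v) <- c(paste0("a_", paper_feature_order()),
                   paste0("b_", paper_feature_order()))
  rownames(v) <- NULL
  labels <- if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL
  if (!is.null(labels) && !all(labels %in% c(0L, 1L)))
    stop("pair labels must be 0 or 1")
  list(vectors = v, labels = labels, pairs = pairs[, c("id_a", "id_b")])
}

#' Serialize a normalizer to a small text file (auditable train/test split)
#' @param params a `minmax_normalizer`
#' @param path output file
#' @export
write_normalizer <- function(params, path) {
  stopifnot(inherits(params, "minmax_normalizer"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# domppi minmax_normalizer y_min=%.17g y_max=%.17g",
                     params$y_min, params$y_max), con)
  tab <- data.frame(feature = names(params$x_min),
                    x_min = sprintf("%.17g", params$x_min),
                    x_max = sprintf("%.17g", params$x_max))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a normalizer written by [write_normalizer()]
#' @param path file path
#' @return a `minmax_normalizer`
#' @export
read_normalizer <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("y_min=([-0-9.eg+]+) y_max=([-0-9.eg+]+)", hdr))[[1L]]
  if (length(m) != 3L) stop("not a normalizer file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(x_min = stats::setNames(tab$x_min, tab$feature),
                 x_max = stats::setNames(tab$x_max, tab$feature),
                 y_min = as.numeric(m[2L]), y_max = as.numeric(m[3L])),
            class = "minmax_normalizer")
}
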