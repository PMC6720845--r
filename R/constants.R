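# Published constant tables (shipped under inst/extdata with citation headers)
# are loaded once per session into this cache.

.domppi_cache <- new.env(parent = emptyenv())

#: standard one-letter amino-acid alphabet, alphabetical
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Mass of one water molecule (Da, average isotopic), restored once per chain
#' @export
WATER_MASS <- 18.0153

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "domppi")
  if (!nzchar(path)) {
    # during in-source development (pkgload) inst/ may be unflattened
    path <- system.file("inst", "extdata", file, package = "domppi")
  }
  if (!nzchar(path)) stop("constant table not found: ", file)
  path
}

.load_table <- function(file) {
  utils::read.table(.extdata(file), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Kyte-Doolittle hydropathy values, named numeric vector of length 20
#' @export
kyte_doolittle <- function() {
  if (is.null(.domppi_cache$kd)) {
    tab <- .load_table("kyte_doolittle.tsv")
    .domppi_cache$kd <- stats::setNames(tab$hydropathy, tab$residue)
  }
  .domppi_cache$kd
}

#' Guruprasad dipeptide instability weight values as a 20 x 20 matrix
#' (rows = first residue of the dipeptide, columns = second)
#' @export
diwv_table <- function() {
  if (is.null(.domppi_cache$diwv)) {
    tab <- .load_table("diwv.tsv")
    m <- matrix(NA_real_, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    m[cbind(tab$first, tab$second)] <- tab$weight
    stopifnot(!anyNA(m))
    .domppi_cache$diwv <- m
  }
  .domppi_cache$diwv
}

#' Bjellqvist pKa set used for the theoretical pI
#'
#' Returns a data frame with columns `group` (Nterm, Cterm, or a residue
#' letter), `pka`, and `sign` (+1 for basic groups, -1 for acidic). The set is
#' swappable: pass a data frame of the same shape to [theoretical_pi()].
#' @export
pka_set <- function() {
  if (is.null(.domppi_cache$pka)) {
    .domppi_cache$pka <- .load_table("pka_bjellqvist.tsv")
  }
  .domppi_cache$pka
}

# average free-amino-acid masses (Da) and atom counts per residue
.residue_constants <- function() {
  if (is.null(.domppi_cache$resconst)) {
    .domppi_cache$resconst <- .load_table("residue_constants.tsv")
  }
  .domppi_cache$resconst
}

residue_masses <- function() {
  tab <- .residue_constants()
  stats::setNames(tab$mass_free, tab$residue)
}

residue_atoms <- function() {
  tab <- .residue_constants()
  stats::setNames(tab$atoms_free, tab$residue)
}
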