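# Factor registry: maps ChIP'd factor names to functional classes. The
# co-occupancy criterion is expressed in classes (>=1 CBX, >=1 RING,
# required histone mark), so additional PRC1 components (HPH, BMI1, MEL18,
# ...) can be added by configuration without code change.

FACTOR_CLASSES <- c("CBX", "RING", "HISTONE_MARK", "OTHER")

#' Build a factor registry
#'
#' @param factors character vector of factor names.
#' @param classes character vector of classes, one of `"CBX"`, `"RING"`,
#'   `"HISTONE_MARK"`, `"OTHER"`.
#' @return A named character vector mapping factor name to class.
#' @export
factor_registry <- function(factors, classes) {
  stopifnot(length(factors) == length(classes))
  if (!all(classes %in% FACTOR_CLASSES))
    stop("unknown factor class: ",
         paste(setdiff(classes, FACTOR_CLASSES), collapse = ", "))
  if (anyDuplicated(factors))
    stop("duplicate factor names in registry")
  setNames(as.character(classes), factors)
}

#' Default registry for the profiled factors
#'
#' CBX6/CBX7/CBX8 are chromobox (Pc ortholog) readers, RING1/RING2 the Sce
#' ortholog E3 ligase subunits, H3K27me3/H3K4me3 histone marks.
#'
#' @return A named character vector (see [factor_registry()]).
#' @export
default_factor_registry <- function() {
  factor_registry(
    c("CBX6", "CBX7", "CBX8", "RING1", "RING2", "H3K27me3", "H3K4me3"),
    c("CBX", "CBX", "CBX", "RING", "RING", "HISTONE_MARK", "HISTONE_MARK")
  )
}

#' Read a factor registry from a two-column TSV or a YAML mapping
#'
#' TSV columns: `factor`, `class` (with header). YAML: a flat
#' `factor: class` mapping.
#'
#' @param path file path ending in `.tsv`/`.txt` or `.yml`/`.yaml`.
#' @return A named character vector (see [factor_registry()]).
#' @export
read_factor_registry <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    m <- yaml::read_yaml(path)
    factor_registry(names(m), unlist(m, use.names = FALSE))
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    factor_registry(d$factor, d$class)
  }
}

registry_class <- function(registry, factors) {
  unknown <- setdiff(factors, names(registry))
  if (length(unknown))
    stop("factor(s) not in registry: ", paste(unknown, collapse = ", "))
  unname(registry[factors])
}
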