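#' @keywords internal
#' @importFrom utils head tail
#' @importFrom stats predict
"_PACKAGE"

# Parameter tables ship as versioned CSVs under inst/extdata/params and are
# cached per session.
.qv_cache <- new.env(parent = emptyenv())

qv_param_table <- function(name) {
  if (!is.null(.qv_cache[[name]])) return(.qv_cache[[name]])
  path <- system.file("extdata", "params", paste0(name, ".csv"),
                      package = "qsarvs", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .qv_cache[[name]] <- tab
  tab
}

#' Element parameter lookup
#'
#' Returns a named per-element value from the shipped element table
#' (atomic number, mass, default valence, van der Waals radius, covalent
#' radius, atomic polarizability).
#'
#' @param elements character vector of element symbols.
#' @param what column name: one of `"z"`, `"mass"`, `"valence"`, `"vdw_r"`,
#'   `"cov_r"`, `"polarizability"`.
#' @return numeric vector aligned with `elements`.
#' @examples
#' element_param(c("C", "O"), "mass")
#' @export
element_param <- function(elements, what) {
  tab <- qv_param_table("elements")
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(what %in% names(tab))
  tab[[what]][idx]
}
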