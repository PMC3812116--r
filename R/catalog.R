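#' Load the packaged Brachyury binding-site catalog
#'
#' The catalog bundles two transcribed knowledge tables: the 16 TNNCAC core
#' hexamers with their representation/requirement status in notochord CRMs
#' (`cores`), and the 24 aligned 12-bp functional Ci-Bra binding sites with
#' their mechanism labels (`sites`). Both are stored as human-readable TSV
#' under `inst/extdata` and validated on load.
#'
#' @param cores_file,sites_file Optional paths overriding the packaged files
#'   (same column schema).
#' @return A list of class `site_catalog` with data frames `cores`
#'   (hexamer, status, evidence, required_in, represented_in) and `sites`
#'   (crm, site12, mechanism), plus `checksum` (md5 of the source files).
#' @examples
#' cat <- site_catalog()
#' table(cat$cores$status)
#' @export
site_catalog <- function(cores_file = NULL, sites_file = NULL) {
  if (is.null(cores_file))
    cores_file <- system.file("extdata", "tbox_cores.tsv", package = "notocrm")
  if (is.null(sites_file))
    sites_file <- system.file("extdata", "functional_sites.tsv",
                              package = "notocrm")
  cores <- utils::read.delim(cores_file, comment.char = "#",
                             stringsAsFactors = FALSE, fill = TRUE)
  for (col in c("required_in", "represented_in"))
    cores[[col]] <- ifelse(is.na(cores[[col]]), "", cores[[col]])
  sites <- utils::read.delim(sites_file, comment.char = "#",
                             stringsAsFactors = FALSE)

  # structural validation: the catalog is ground truth, so fail loudly
  if (nrow(cores) != 16L || anyDuplicated(cores$hexamer))
    stop("core catalog must contain exactly the 16 TNNCAC hexamers")
  if (!all(vapply(cores$hexamer, pattern_match, logical(1),
                  pattern = core_pattern())))
    stop("core catalog contains a non-TNNCAC hexamer")
  if (!all(cores$status %in% c("required", "represented_only", "unobserved")))
    stop("invalid status in core catalog")
  if (nrow(sites) != 24L)
    stop("functional-site catalog must contain exactly 24 sites")
  core5to10 <- toupper(substr(sites$site12, 5L, 10L))
  if (!all(vapply(core5to10, pattern_match, logical(1),
                  pattern = core_pattern())))
    stop("a functional site lacks a TNNCAC core at alignment positions 5-10")
  if (!all(sites$mechanism %in% c("individual", "cooperative")))
    stop("invalid mechanism in functional-site catalog")

  structure(list(cores = cores, sites = sites,
                 checksum = unname(tools::md5sum(c(cores_file, sites_file)))),
            class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat("Brachyury binding-site catalog\n")
  cat("  cores:", nrow(x$cores), "TNNCAC hexamers (",
      sum(x$cores$status == "required"), "required )\n")
  cat("  functional sites:", nrow(x$sites), "12-bp sites from",
      length(unique(x$sites$crm)), "CRMs\n")
  invisible(x)
}

#' Requirement status of a core hexamer
#'
#' @param hexamer 6-base DNA string matching TNNCAC.
#' @param catalog A [site_catalog()].
#' @return One of `"required"`, `"represented_only"`, `"unobserved"`.
#' @examples
#' core_status("TAACAC")  # "required"
#' core_status("TTCCAC")  # "unobserved"
#' @export
core_status <- function(hexamer, catalog = site_catalog()) {
  hexamer <- toupper(hexamer)
  if (!pattern_match(hexamer, core_pattern()))
    stop("hexamer does not match the TNNCAC core: ", hexamer)
  catalog$cores$status[match(hexamer, catalog$cores$hexamer)]
}

#' Core hexamers in a given whitelist mode
#'
#' @param mode `"required_only"` (the 9 required cores) or
#'   `"required_plus_represented"` (15 cores; everything observed in a CRM).
#' @param catalog A [site_catalog()].
#' @return Character vector of hexamers.
#' @export
core_whitelist <- function(mode = c("required_only", "required_plus_represented"),
                           catalog = site_catalog()) {
  mode <- match.arg(mode)
  keep <- if (mode == "required_only") "required"
          else c("required", "represented_only")
  catalog$cores$hexamer[catalog$cores$status %in% keep]
}

#' Lowercase positions of a printed functional site
#'
#' Helper for the case-pattern regression: the positions at which a catalog
#' `site12` entry is printed in lowercase (bases flagged as diverging from
#' the extended consensus).
#'
#' @param site12 12-base string with case preserved as printed.
#' @return Integer vector of 1-based positions.
#' @export
lowercase_positions <- function(site12) {
  s <- strsplit(site12, "")[[1]]
  which(s %in% letters)
}
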