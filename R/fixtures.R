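# Content hashes of the packaged worked-example fixtures; load_fixture()
# refuses silently corrupted copies.
.fixture_md5 <- c(
  table2_components = "23b5459ec8ef50480614e1cd25997db7",
  table3_chains = "30a15dfe01c943e31f7da4f74ec5bb56"
)

#' Load a packaged worked-example fixture
#'
#' Two transcribed tables ship with the package:
#' \describe{
#' \item{`table2_components`}{97 screened herb components (68 primary-herb
#'   "LGT" rows, 29 helper-herb "JQC" rows) with ADMET properties. One row
#'   of the published table has no identifier; it carries the placeholder
#'   id `MIDNA001`.}
#' \item{`table3_chains`}{50 representative scored gene transmission
#'   chains with the nine score columns (initial value, chain, spread,
#'   loss, tox_begin/fin, JQC_begin/fin, final). Returned with numeric
#'   score columns and, as attribute `"chains"`, the chain strings parsed
#'   into labeled [gene_chain()] objects.}
#' }
#' Files are content-hashed; a checksum mismatch raises an error.
#'
#' @param name `"table2_components"` or `"table3_chains"`.
#' @return A data frame (see Details).
#' @export
load_fixture <- function(name = c("table2_components", "table3_chains")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "etnet",
                      mustWork = TRUE)
  hash <- unname(tools::md5sum(path))
  if (!identical(hash, unname(.fixture_md5[name]))) {
    stop("fixture '", name, "' failed its checksum (expected ",
         .fixture_md5[name], ", got ", hash, ")")
  }
  if (name == "table2_components") {
    read_components(path)
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
    num <- setdiff(names(x), "chain")
    for (col in num) x[[col]] <- as.numeric(x[[col]])
    attr(x, "chains") <- lapply(x$chain, parse_chain)
    x
  }
}

#' Verify the score identities of the packaged chain fixture
#'
#' Recomputes, for every row of the `table3_chains` fixture, the final
#' score from its parts (`fin = spread - tox_fin + JQC_fin` via
#' [combine_chain_score()]) and the loss (`loss = initial - spread`), and
#' compares both with the printed columns.
#'
#' @param tol allowed absolute discrepancy (printed values carry 2
#'   decimals; default 0.02).
#' @return Data frame with per-row recomputed values, absolute errors and
#'   a logical `ok` column; attribute `"all_ok"` summarizes.
#' @export
verify_fixture_scores <- function(tol = 0.02) {
  x <- load_fixture("table3_chains")
  fin <- combine_chain_score(x[["Spread value"]], x[["tox_fin value"]],
                             x[["JQC_fin value"]])
  loss <- x[["inital_value"]] - x[["Spread value"]]
  out <- data.frame(
    chain = x$chain,
    fin_value = x$fin_value, fin_recomputed = fin,
    fin_err = abs(fin - x$fin_value),
    loss_value = x[["Loss value"]], loss_recomputed = loss,
    loss_err = abs(loss - x[["Loss value"]]),
    stringsAsFactors = FALSE, check.names = FALSE)
  out$ok <- out$fin_err <= tol & out$loss_err <= tol
  attr(out, "all_ok") <- all(out$ok)
  out
}
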