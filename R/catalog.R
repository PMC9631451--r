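#' ADMET screening criteria
#'
#' Bundle of rule-based thresholds used to select drug-like ("active")
#' herb components. All numeric bounds are inclusive: a component passes the
#' molecular-weight rule when `mw <= mw_max`, and likewise for the count
#' rules. The gastrointestinal-absorption rule requires the class given in
#' `gi_required`; the hERG rule excludes only the classes in `herg_exclude`
#' (cardiotoxicity proxy), so `medium_risk` and `ambiguous` components pass
#' by default.
#'
#' @param mw_max maximum molecular weight in Da.
#' @param hdon_max maximum number of hydrogen-bond donors.
#' @param hacc_max maximum number of hydrogen-bond acceptors.
#' @param rbn_max maximum number of rotatable bonds.
#' @param gi_required required gastrointestinal-absorption class.
#' @param herg_exclude hERG-inhibition risk classes that disqualify a
#'   component.
#' @return An object of class `admet_criteria` (a named list).
#' @export
admet_criteria <- function(mw_max = 500, hdon_max = 5, hacc_max = 10,
                           rbn_max = 10, gi_required = "High",
                           herg_exclude = "high_risk") {
  structure(list(mw_max = mw_max, hdon_max = hdon_max, hacc_max = hacc_max,
                 rbn_max = rbn_max, gi_required = gi_required,
                 herg_exclude = herg_exclude),
            class = "admet_criteria")
}

.gi_levels   <- c("High", "Low")
.herg_levels <- c("low_risk", "medium_risk", "high_risk", "ambiguous")
.component_cols <- c("id", "herb", "name", "mw", "hdon", "hacc", "rbn",
                     "fsp3", "gi", "herg")

#' Validate a component property table
#'
#' Checks the column contract of a component table (one herb constituent per
#' row with its ADMET properties) and coerces numeric columns. Rows with
#' out-of-vocabulary class labels or impossible numeric values raise an
#' error; missing values are allowed (the screen rejects such rows as
#' incomplete rather than failing).
#'
#' @param components data frame with columns
#'   `id, herb, name, mw, hdon, hacc, rbn, fsp3, gi, herg`.
#' @return The validated data frame.
#' @export
validate_components <- function(components) {
  stopifnot(is.data.frame(components))
  missing_cols <- setdiff(.component_cols, names(components))
  if (length(missing_cols)) {
    stop("component table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  for (col in c("mw", "hdon", "hacc", "rbn", "fsp3")) {
    components[[col]] <- as.numeric(components[[col]])
  }
  ok <- function(x, test) all(test(x[!is.na(x)]))
  if (!ok(components$mw, function(x) x > 0)) stop("mw must be positive")
  for (col in c("hdon", "hacc", "rbn")) {
    if (!ok(components[[col]], function(x) x >= 0 & x == round(x))) {
      stop(col, " must be a nonnegative integer count")
    }
  }
  if (!ok(components$fsp3, function(x) x >= 0 & x <= 1)) {
    stop("fsp3 must lie in [0, 1]")
  }
  if (!ok(components$gi, function(x) x %in% .gi_levels)) {
    stop("gi must be one of: ", paste(.gi_levels, collapse = ", "))
  }
  if (!ok(components$herg, function(x) x %in% .herg_levels)) {
    stop("herg must be one of: ", paste(.herg_levels, collapse = ", "))
  }
  components
}

#' Read a component property table from TSV
#'
#' @param path TSV file with header
#'   `id, herb, name, mw, hdon, hacc, rbn, fsp3, gi, herg`.
#' @return Validated component data frame.
#' @export
read_components <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         comment.char = "", check.names = TRUE,
                         fileEncoding = "UTF-8")
  validate_components(x)
}

#' Rule-based ADMET screen
#'
#' Partitions a component table into components passing all criteria and
#' rejected components, each rejected row carrying the list of violated
#' rules. A component with a missing value in any screened property is
#' rejected with reason `"incomplete record"`. Screening is idempotent, and
#' relaxing any single criterion can only grow the passing set.
#'
#' @param components validated component data frame
#'   (see [validate_components()]).
#' @param criteria an [admet_criteria()] object.
#' @return A list with elements `passing` (data frame), `rejected`
#'   (data frame with an extra `reasons` column, a semicolon-joined string),
#'   and `criteria`.
#' @export
admet_screen <- function(components, criteria = admet_criteria()) {
  components <- validate_components(components)
  stopifnot(inherits(criteria, "admet_criteria"))
  n <- nrow(components)
  reasons <- vector("list", n)
  screened <- c("mw", "hdon", "hacc", "rbn", "gi", "herg")
  for (i in seq_len(n)) {
    row <- components[i, ]
    if (anyNA(row[screened]) || any(!nzchar(as.character(row[c("gi", "herg")])))) {
      reasons[[i]] <- "incomplete record"
      next
    }
    viol <- character(0)
    if (row$mw > criteria$mw_max)     viol <- c(viol, sprintf("mw > %g", criteria$mw_max))
    if (row$hdon > criteria$hdon_max) viol <- c(viol, sprintf("hdon > %g", criteria$hdon_max))
    if (row$hacc > criteria$hacc_max) viol <- c(viol, sprintf("hacc > %g", criteria$hacc_max))
    if (row$rbn > criteria$rbn_max)   viol <- c(viol, sprintf("rbn > %g", criteria$rbn_max))
    if (row$gi != criteria$gi_required) viol <- c(viol, sprintf("gi != %s", criteria$gi_required))
    if (row$herg %in% criteria$herg_exclude) viol <- c(viol, sprintf("herg in {%s}", paste(criteria$herg_exclude, collapse = ",")))
    reasons[[i]] <- viol
  }
  fail <- lengths(reasons) > 0
  rejected <- components[fail, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reasons <- vapply(reasons[fail], paste, character(1), collapse = "; ")
  } else {
    rejected$reasons <- character(0)
  }
  list(passing = components[!fail, , drop = FALSE],
       rejected = rejected,
       criteria = criteria)
}

#' Partition components of two herbs into shared and unique sets
#'
#' Component identity is the `id` column, not the display name. The summary
#' also reports the multiset size (rows across both herbs) next to the
#' number of distinct entities, since a shared component is counted once per
#' herb in the former.
#'
#' @param herbA,herbB component data frames (or anything with an `id`
#'   column), one per herb.
#' @return A list with character-vector elements `shared`, `uniqueA`,
#'   `uniqueB` and a `summary` list (`n_A`, `n_B`, `n_shared`,
#'   `n_multiset`, `n_entities`).
#' @export
partition_components <- function(herbA, herbB) {
  ids <- function(x, label) {
    v <- if (is.data.frame(x)) as.character(x$id) else as.character(x)
    dup <- unique(v[duplicated(v)])
    if (length(dup)) {
      stop("duplicate component id within ", label, ": ",
           paste(dup, collapse = ", "))
    }
    v
  }
  a <- ids(herbA, "herbA")
  b <- ids(herbB, "herbB")
  shared <- sort(intersect(a, b))
  list(shared = shared,
       uniqueA = sort(setdiff(a, b)),
       uniqueB = sort(setdiff(b, a)),
       summary = list(n_A = length(a), n_B = length(b),
                      n_shared = length(shared),
                      n_multiset = length(a) + length(b),
                      n_entities = length(union(a, b))))
}

#' Read a toxicity annotation table from TSV
#'
#' @param path TSV with header `gene, effect, system, n_reports`: one row
#'   per (gene, adverse-effect term) with the organ system affected and the
#'   number of literature reports.
#' @return Data frame.
#' @export
read_tox_annotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         fileEncoding = "UTF-8")
  need <- c("gene", "effect", "system", "n_reports")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("toxicity annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x$n_reports <- as.numeric(x$n_reports)
  if (any(x$n_reports < 0, na.rm = TRUE)) stop("n_reports must be >= 0")
  x
}

#' Select toxic targets from adverse-reaction annotations
#'
#' A gene qualifies as a toxic target when its adverse reactions span at
#' least `min_systems` distinct organ systems and its total literature
#' report count strictly exceeds `min_reports`.
#'
#' @param annotations data frame with columns `gene, effect, system,
#'   n_reports` (see [read_tox_annotations()]).
#' @param min_systems minimum number of distinct organ systems (default 2,
#'   i.e. "multiple systems").
#' @param min_reports report-count threshold; selection requires a strictly
#'   greater total (default 10).
#' @return Sorted character vector of gene symbols.
#' @export
select_toxic_targets <- function(annotations, min_systems = 2, min_reports = 10) {
  stopifnot(min_systems >= 1, min_reports >= 0)
  if (is.null(annotations) || nrow(annotations) == 0) return(character(0))
  systems <- tapply(annotations$system, annotations$gene,
                    function(s) length(unique(s)))
  reports <- tapply(annotations$n_reports, annotations$gene, sum)
  genes <- names(systems)
  sort(genes[systems >= min_systems & reports > min_reports])
}
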