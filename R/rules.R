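#' @title Biotransformation rules
#' @description Phase I/II metabolic transformations expressed as elemental
#'   formula deltas. Applying a rule to a neutral formula adds and removes
#'   the stated element counts; chemically infeasible applications (negative
#'   counts) are pruned by the enumeration engine.
#' @name rules
NULL

#' Create a transformation rule
#'
#' @param name Unique rule name, e.g. "O-demethylation".
#' @param add,remove Formula strings (or \code{chem_formula}) added/removed;
#'   at least one non-empty.
#' @param phase "I" (functionalisation) or "II" (conjugation). Phase II
#'   rules are applied at most once and only as the terminal step of a
#'   transformation path.
#' @param max_n Maximum applications of this rule along one path.
#' @param artifact Flag for transformations regarded as analytical
#'   artifacts (e.g. methyl esters formed during workup) rather than true
#'   metabolic steps; artifact-derived candidates are excluded from
#'   screening panels by default.
#' @return A \code{transformation_rule}.
#' @export
transformation_rule <- function(name, add = NULL, remove = NULL,
                                phase = c("I", "II"), max_n = 1L,
                                artifact = FALSE) {
  phase <- match.arg(phase)
  parse0 <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- parse_formula(x)
    x
  }
  add <- parse0(add); remove <- parse0(remove)
  if (is.null(add) && is.null(remove)) {
    stop("a rule must add or remove at least one atom", call. = FALSE)
  }
  structure(list(name = name, add = add, remove = remove, phase = phase,
                 max_n = as.integer(max_n), artifact = isTRUE(artifact)),
            class = "transformation_rule")
}

apply_rule <- function(formula, rule) {
  f <- formula
  if (!is.null(rule$remove)) f <- subtract_formula(f, rule$remove)
  if (!is.null(rule$add)) f <- add_formula(f, rule$add)
  f
}

#' Default phase I/II rule set
#'
#' The transformation vocabulary known for arylcyclohexylamine (PCP-type)
#' drugs: O-demethylation, aliphatic/aromatic hydroxylation (up to three
#' sites), dehydrogenation, oxidation to an oxo group, carboxylation after
#' ring opening, methyl-ester formation (flagged as an analytical artifact)
#' and terminal glucuronidation.
#'
#' @return Named list of [transformation_rule()] objects.
#' @export
#' @examples
#' names(default_rule_set())
default_rule_set <- function() {
  rules <- list(
    transformation_rule("O-demethylation", remove = "CH2", max_n = 1L),
    transformation_rule("hydroxylation", add = "O", max_n = 3L),
    transformation_rule("dehydrogenation", remove = "H2", max_n = 2L),
    transformation_rule("oxidation-to-oxo", add = "O", remove = "H2",
                        max_n = 2L),
    transformation_rule("carboxylation", add = "O2", max_n = 1L),
    transformation_rule("methylation-artifact", add = "CH2", max_n = 1L,
                        artifact = TRUE),
    transformation_rule("glucuronidation", add = "C6H8O6", phase = "II",
                        max_n = 1L)
  )
  names(rules) <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(names(rules))) stop("rule names must be unique")
  rules
}

#' Enumerate candidate metabolite formulas
#'
#' Generates all distinct neutral formulas reachable from a parent by at
#' most \code{depth} phase I rule applications (respecting each rule's
#' \code{max_n}), optionally followed by a single terminal phase II
#' conjugation. The conjugation step does not count against \code{depth}:
#' depth bounds the length of the oxidative chain on the aglycone, and
#' each conjugate corresponds one-to-one with its aglycone. Duplicate
#' formulas arising from different paths are merged with all generating
#' paths retained.
#'
#' @param parent Neutral parent formula (\code{chem_formula} or string).
#' @param rules Rule list from [default_rule_set()].
#' @param depth Maximum number of phase I applications (>= 0).
#' @param constants Constants list.
#' @return Data.frame with columns \code{formula} (neutral),
#'   \code{mh_formula}, \code{mh_mz}, \code{phase} ("parent", "I" or "II"),
#'   \code{n_steps} (minimal path length counting the conjugation),
#'   \code{artifact} (TRUE iff every generating path uses an artifact
#'   rule), and \code{paths} (list-column of character vectors of rule
#'   names).
#' @export
#' @examples
#' head(enumerate_candidates("C18H27NO", depth = 2))
enumerate_candidates <- function(parent, rules = default_rule_set(),
                                 depth = 3L,
                                 constants = default_constants()) {
  if (is.character(parent)) parent <- parse_formula(parent)
  depth <- as.integer(depth)
  if (depth < 0L) stop("depth must be >= 0", call. = FALSE)
  p1 <- Filter(function(r) r$phase == "I", rules)
  p2 <- Filter(function(r) r$phase == "II", rules)

  # multiset enumeration of phase I applications: non-decreasing rule index
  # sequences, so each combination is visited once
  outcomes <- list(list(formula = parent, path = character(0)))
  recurse <- function(f, path, start, counts, d) {
    if (d == 0L) return()
    for (i in seq_along(p1)[seq_along(p1) >= start]) {
      r <- p1[[i]]
      if (counts[i] >= r$max_n) next
      fi <- tryCatch(apply_rule(f, r), error = function(e) NULL)
      if (is.null(fi)) next
      counts2 <- counts; counts2[i] <- counts2[i] + 1L
      outcomes[[length(outcomes) + 1L]] <<-
        list(formula = fi, path = c(path, r$name))
      recurse(fi, c(path, r$name), i, counts2, d - 1L)
    }
  }
  recurse(parent, character(0), 1L, integer(length(p1)), depth)

  # terminal phase II conjugation of every phase I outcome (and the parent)
  n1 <- length(outcomes)
  for (k in seq_len(n1)) {
    for (r in p2) {
      fi <- tryCatch(apply_rule(outcomes[[k]]$formula, r),
                     error = function(e) NULL)
      if (is.null(fi)) next
      outcomes[[length(outcomes) + 1L]] <-
        list(formula = fi, path = c(outcomes[[k]]$path, r$name))
    }
  }

  keys <- vapply(outcomes, function(o) format(o$formula), "")
  artifact_rules <- names(Filter(function(r) r$artifact, rules))
  uniq <- !duplicated(keys)
  res <- lapply(which(uniq), function(i) {
    sel <- which(keys == keys[i])
    paths <- lapply(outcomes[sel], `[[`, "path")
    lens <- lengths(paths)
    has_p2 <- vapply(paths, function(p) any(p %in% names(p2)), TRUE)
    phase <- if (all(lens == 0)) "parent" else if (any(has_p2)) "II" else "I"
    f <- outcomes[[i]]$formula
    ionf <- add_formula(f, new_chem_formula(c(H = 1L)))
    list(formula = format(f), mh_formula = format(ionf),
         mh_mz = exact_mass(ion_species(ionf), constants = constants),
         phase = phase, n_steps = min(lens),
         artifact = all(vapply(paths, function(p)
           any(p %in% artifact_rules), TRUE)) && length(paths) > 0 &&
           any(lens > 0),
         paths = paths)
  })
  out <- data.frame(
    formula = vapply(res, `[[`, "", "formula"),
    mh_formula = vapply(res, `[[`, "", "mh_formula"),
    mh_mz = vapply(res, `[[`, 0, "mh_mz"),
    phase = vapply(res, `[[`, "", "phase"),
    n_steps = vapply(res, `[[`, 0L, "n_steps"),
    artifact = vapply(res, `[[`, TRUE, "artifact"),
    stringsAsFactors = FALSE)
  out$paths <- lapply(res, `[[`, "paths")
  out[order(out$mh_mz), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
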