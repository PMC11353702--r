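# Atom selection: small combinable predicate objects over topology fields.
# Selections evaluate to ordered, duplicate-free 1-based atom indices (the
# positional indices used by every coordinate array in the package).

.SEL_FIELDS <- c("residue_name", "atom_name", "residue_id", "chain_id",
                 "element", "atom_id")

#' Build an atomic selection predicate
#'
#' Each supplied field restricts the match; multiple fields are combined
#' with AND.  `residue_id` accepts vectors of residue numbers (ranges via
#' `seq`/`:`).  Combine specs with [sel_and()], [sel_or()], [sel_not()].
#'
#' @param ... named field constraints, e.g.
#'   `sel(residue_name = c("GLU", "ASP"), atom_name = c("OD1", "OD2"))`.
#' @return object of class `SelectionSpec`.
#' @export
sel <- function(...) {
  fields <- list(...)
  if (length(fields)) {
    bad <- setdiff(names(fields), .SEL_FIELDS)
    if (length(bad) || is.null(names(fields)) || any(names(fields) == ""))
      stop("unknown selection field(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           " (known: ", paste(.SEL_FIELDS, collapse = ", "), ")")
  }
  structure(list(op = "match", fields = fields), class = "SelectionSpec")
}

#' @rdname sel
#' @export
sel_all <- function() sel()

#' Combine selection predicates
#'
#' @param ... `SelectionSpec` objects.
#' @param spec a `SelectionSpec`.
#' @return a combined `SelectionSpec`.
#' @export
sel_and <- function(...) structure(list(op = "and", parts = list(...)),
                                   class = "SelectionSpec")

#' @rdname sel_and
#' @export
sel_or <- function(...) structure(list(op = "or", parts = list(...)),
                                  class = "SelectionSpec")

#' @rdname sel_and
#' @export
sel_not <- function(spec) structure(list(op = "not", parts = list(spec)),
                                    class = "SelectionSpec")

.eval_spec <- function(spec, atoms) {
  if (!inherits(spec, "SelectionSpec")) stop("not a SelectionSpec")
  switch(spec$op,
    match = {
      keep <- rep(TRUE, nrow(atoms))
      for (nm in names(spec$fields))
        keep <- keep & (atoms[[nm]] %in% spec$fields[[nm]])
      keep
    },
    and = Reduce(`&`, lapply(spec$parts, .eval_spec, atoms = atoms)),
    or  = Reduce(`|`, lapply(spec$parts, .eval_spec, atoms = atoms)),
    not = !.eval_spec(spec$parts[[1]], atoms),
    stop("unknown selection op: ", spec$op))
}

#' Evaluate a selection on a topology
#'
#' @param topology a [new_topology()] object.
#' @param spec a [sel()] / [sel_and()] combination.
#' @return sorted, duplicate-free integer vector of 1-based atom indices
#'   (may be empty).
#' @export
select_atoms <- function(topology, spec) {
  which(.eval_spec(spec, topology$atoms))
}
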