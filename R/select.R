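# Atom selection by conjunction of simple clauses.

#' Select atoms
#'
#' Returns the atoms satisfying the conjunction of the given clauses, in
#' input order.  Supported keys: `name`, `element`, `resname`, `resno`
#' (value or range vector), `chain`, `tag` (exact tag membership) and
#' `rindex`.  An empty query selects all atoms.
#'
#' @param x a `mol_structure`.
#' @param ... named clauses, e.g. `element = "P"`, `resno = 3:8`,
#'   `tag = "func:NH3+"`.
#' @param as_structure if `TRUE` return a `mol_structure` restricted to
#'   the selection instead of the atom table.
#' @return data.frame of matching atom records (or a `mol_structure`).
#' @export
select_atoms <- function(x, ..., as_structure = FALSE) {
  cl <- list(...)
  allowed <- c("name", "element", "resname", "resno", "chain", "tag",
               "rindex")
  bad <- setdiff(names(cl), allowed)
  if (length(bad) > 0 || (length(cl) > 0 && is.null(names(cl))))
    stop("unknown selection key(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  for (k in names(cl)) {
    v <- cl[[k]]
    keep <- keep & switch(k,
      name = a$name %in% v,
      element = a$element %in% v,
      resname = a$resname %in% v,
      resno = a$resno %in% v,
      chain = a$chain %in% v,
      rindex = a$rindex %in% v,
      tag = {
        m <- rep(FALSE, nrow(a))
        for (tg in v) m <- m | has_tag(x, tg)
        m
      })
  }
  out <- a[keep, , drop = FALSE]
  if (!as_structure) return(out)
  y <- x
  y$atoms <- out
  if (!is.null(y$bonds) && length(y$bonds) > 0) {
    ok <- y$bonds[, 1] %in% out$serial & y$bonds[, 2] %in% out$serial
    y$bonds <- y$bonds[ok, , drop = FALSE]
  }
  y
}
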