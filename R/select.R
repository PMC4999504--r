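# Selection mini-grammar over group_tag, element, residue_name, molecule_id,
# with periodic "within <d> of <expr>" shells. Examples:
#   "group water"
#   "group water within 5.0 of group hydrophilic_head"
#   "element O and resname LYS"
#   "not (group water) or molid 3"
#
# "A within d of B" keeps the atoms of A belonging to molecules that have at
# least one A-atom within d (minimum image) of any atom of B: shells are
# completed to whole molecules so a water whose oxygen sits inside the shell
# contributes all of its atoms.

.tokenize_selection <- function(expr) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1) stop("selection parse error: empty expression")
  data.frame(tok = regmatches(expr, gregexpr(pat, expr, perl = TRUE))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

.sel_error <- function(msg, toks, i) {
  pos <- if (i <= nrow(toks)) toks$pos[i] else nchar(paste(toks$tok, collapse = " "))
  stop("selection parse error at position ", pos, ": ", msg, call. = FALSE)
}

# Recursive-descent parser producing a nested list AST.
.parse_selection <- function(expr) {
  toks <- .tokenize_selection(expr)
  i <- 1L
  peek <- function() if (i <= nrow(toks)) toks$tok[i] else NA_character_
  advance <- function() { t <- peek(); i <<- i + 1L; t }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what) .sel_error(paste0("expected '", what, "'"), toks, i - 1L)
    t
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      node <- list(op = "or", a = node, b = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_within()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      node <- list(op = "and", a = node, b = parse_within())
    }
    node
  }
  parse_within <- function() {
    node <- parse_unary()
    if (!is.na(peek()) && peek() == "within") {
      advance()
      d <- suppressWarnings(as.numeric(advance()))
      if (is.na(d) || d < 0) .sel_error("'within' needs a nonnegative distance", toks, i - 1L)
      expect("of")
      node <- list(op = "within", d = d, a = node, b = parse_unary())
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) .sel_error("unexpected end of expression", toks, i)
    if (t == "not") { advance(); return(list(op = "not", a = parse_unary())) }
    if (t == "(") {
      advance()
      node <- parse_or()
      expect(")")
      return(node)
    }
    advance()
    if (t == "all") return(list(op = "all"))
    val <- advance()
    if (is.na(val)) .sel_error(paste0("'", t, "' needs an argument"), toks, i - 1L)
    switch(t,
      group = list(op = "group", val = val),
      element = list(op = "element", val = val),
      resname = list(op = "resname", val = val),
      molid = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) .sel_error("'molid' needs an integer", toks, i - 1L)
        list(op = "molid", val = v)
      },
      .sel_error(paste0("unknown keyword '", t, "'"), toks, i - 2L))
  }
  node <- parse_or()
  if (!is.na(peek())) .sel_error(paste0("trailing input '", peek(), "'"), toks, i)
  node
}

.eval_selection <- function(node, top, fr) {
  a <- top$atoms
  switch(node$op,
    all = a$atom_id,
    group = a$atom_id[a$group_tag == node$val],
    element = a$atom_id[toupper(a$element) == toupper(node$val)],
    resname = a$atom_id[a$residue_name == node$val],
    molid = a$atom_id[a$molecule_id == node$val],
    not = setdiff(a$atom_id, .eval_selection(node$a, top, fr)),
    and = intersect(.eval_selection(node$a, top, fr),
                    .eval_selection(node$b, top, fr)),
    or = union(.eval_selection(node$a, top, fr),
               .eval_selection(node$b, top, fr)),
    within = {
      ids_a <- .eval_selection(node$a, top, fr)
      ids_b <- .eval_selection(node$b, top, fr)
      if (!length(ids_a) || !length(ids_b)) return(integer(0))
      if (is.null(fr)) stop("'within' selections need a frame")
      d <- min_image_dist(fr$coords[ids_a, , drop = FALSE],
                          fr$coords[ids_b, , drop = FALSE], fr$box)
      hit <- ids_a[apply(d <= node$d, 1, any)]
      keep_mol <- unique(a$molecule_id[hit])
      ids_a[a$molecule_id[ids_a] %in% keep_mol]
    },
    stop("internal: unknown AST op ", node$op))
}

#' Select atoms with the selection mini-language
#'
#' Evaluates a selection expression against a topology and (for `within`
#' shells) a frame, returning a deterministic sorted set of atom ids.
#' `within` uses minimum-image distances and completes hits to whole
#' molecules of the left-hand operand.
#'
#' @param top a `topology`.
#' @param fr a `frame`; may be `NULL` for purely static expressions.
#' @param expr selection string; see the grammar in the package vignette.
#' @return sorted integer vector of atom ids.
#' @export
select_atoms <- function(top, fr, expr) {
  if (is.numeric(expr)) return(sort(unique(as.integer(expr))))
  node <- .parse_selection(expr)
  sort(unique(as.integer(.eval_selection(node, top, fr))))
}

# resolve an atom-id vector or selection string; used by every analysis entry
.resolve_sel <- function(top, fr, sel, what = "selection") {
  ids <- select_atoms(top, fr, sel)
  if (!length(ids)) stop("empty ", what, if (is.character(sel)) paste0(": ", sel) else "")
  ids
}
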