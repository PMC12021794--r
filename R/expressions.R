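# Logical expression trees and their canonical disjunctive normal form.
#
# Trees are plain lists: list(kind = "and"|"or"|"not", args = list(...)),
# list(kind = "var", name = "g1"), or list(kind = "const", value = 0L|1L).
# A DNF is a list of clauses; a clause is a named integer vector mapping
# component names to 1 (plain literal) or 0 (negated literal), with names
# sorted in C-locale (radix) order.  The clause list itself is sorted by the
# clause key string, so clause indices are a stable file-format contract.

.exprVar <- function(name) list(kind = "var", name = name)
.exprConst <- function(value) list(kind = "const", value = as.integer(value))
.exprNot <- function(e) list(kind = "not", args = list(e))
.exprAnd <- function(args) if (length(args) == 1L) args[[1L]] else list(kind = "and", args = args)
.exprOr <- function(args) if (length(args) == 1L) args[[1L]] else list(kind = "or", args = args)

# --- tokenizer / recursive-descent parser for the bnet rule dialect -------

.tokenizeRule <- function(text, where = "rule") {
  chars <- strsplit(text, "")[[1L]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[[:space:]]$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("&", "|", "!", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch)
      i <- i + 1L
    } else if (ch %in% c("0", "1") &&
               (i == n || !grepl("^[A-Za-z0-9_.]$", chars[i + 1L]))) {
      toks[[length(toks) + 1L]] <- list(type = "const", value = as.integer(ch))
      i <- i + 1L
    } else if (grepl("^[A-Za-z_.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "name",
                                        name = paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else {
      stop(sprintf("unexpected character '%s' in %s", ch, where), call. = FALSE)
    }
  }
  toks
}

.parseRule <- function(text, where = "rule") {
  toks <- .tokenizeRule(text, where)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else NA_character_
  take <- function() {
    tk <- toks[[pos]]
    pos <<- pos + 1L
    tk
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (identical(peek(), "|")) {
      take()
      args[[length(args) + 1L]] <- parseAnd()
    }
    .exprOr(args)
  }
  parseAnd <- function() {
    args <- list(parseAtom())
    while (identical(peek(), "&")) {
      take()
      args[[length(args) + 1L]] <- parseAtom()
    }
    .exprAnd(args)
  }
  parseAtom <- function() {
    tp <- peek()
    if (is.na(tp)) stop(sprintf("unexpected end of expression in %s", where), call. = FALSE)
    if (tp == "!") {
      take()
      return(.exprNot(parseAtom()))
    }
    if (tp == "(") {
      take()
      e <- parseOr()
      if (!identical(peek(), ")")) {
        stop(sprintf("missing ')' in %s", where), call. = FALSE)
      }
      take()
      return(e)
    }
    if (tp == "name") return(.exprVar(take()$name))
    if (tp == "const") return(.exprConst(take()$value))
    stop(sprintf("unexpected token '%s' in %s", tp, where), call. = FALSE)
  }
  e <- parseOr()
  if (pos <= length(toks)) {
    stop(sprintf("trailing input after expression in %s", where), call. = FALSE)
  }
  e
}

# --- evaluation -----------------------------------------------------------

# Evaluate a tree on a 0/1 matrix with one column per component (columns
# named); returns an integer 0/1 vector with one entry per row.
.evalExpr <- function(e, mat) {
  switch(e$kind,
    var = {
      if (!e$name %in% colnames(mat)) {
        stop(sprintf("unknown component '%s' in expression", e$name), call. = FALSE)
      }
      as.integer(mat[, e$name])
    },
    const = rep.int(e$value, nrow(mat)),
    not = 1L - .evalExpr(e$args[[1L]], mat),
    and = {
      v <- .evalExpr(e$args[[1L]], mat)
      for (a in e$args[-1L]) v <- v & .evalExpr(a, mat)
      as.integer(v)
    },
    or = {
      v <- .evalExpr(e$args[[1L]], mat)
      for (a in e$args[-1L]) v <- v | .evalExpr(a, mat)
      as.integer(v)
    },
    stop("corrupt expression tree", call. = FALSE)
  )
}

.exprSupport <- function(e) {
  switch(e$kind,
    var = e$name,
    const = character(0),
    unique(unlist(lapply(e$args, .exprSupport)))
  )
}

# --- negation normal form and DNF -----------------------------------------

.toNNF <- function(e, negate = FALSE) {
  switch(e$kind,
    var = if (negate) .exprNot(e) else e,
    const = .exprConst(if (negate) 1L - e$value else e$value),
    not = .toNNF(e$args[[1L]], !negate),
    and = {
      args <- lapply(e$args, .toNNF, negate = negate)
      if (negate) .exprOr(args) else .exprAnd(args)
    },
    or = {
      args <- lapply(e$args, .toNNF, negate = negate)
      if (negate) .exprAnd(args) else .exprOr(args)
    }
  )
}

.clauseKey <- function(clause) {
  if (length(clause) == 0L) return("")
  paste(ifelse(clause == 1L, names(clause), paste0("!", names(clause))),
        collapse = "&")
}

# Merge two clauses; NULL when they contain complementary literals.
.mergeClauses <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (any(a[common] != b[common])) return(NULL)
  m <- c(a, b[setdiff(names(b), names(a))])
  m[order(names(m), method = "radix")]
}

# Distribute an NNF tree into a raw clause list (no simplification yet).
.nnfClauses <- function(e) {
  switch(e$kind,
    var = list(stats::setNames(1L, e$name)),
    not = list(stats::setNames(0L, e$args[[1L]]$name)),
    const = if (e$value == 1L) list(stats::setNames(integer(0), character(0))) else list(),
    or = do.call(c, lapply(e$args, .nnfClauses)),
    and = {
      acc <- list(stats::setNames(integer(0), character(0)))
      for (a in e$args) {
        sub <- .nnfClauses(a)
        out <- list()
        for (cl1 in acc) {
          for (cl2 in sub) {
            m <- .mergeClauses(cl1, cl2)
            if (!is.null(m)) out[[length(out) + 1L]] <- m
          }
        }
        acc <- out
        if (length(acc) == 0L) break
      }
      acc
    }
  )
}

# Canonical DNF: distribute, drop contradictions, absorb supersets, sort.
.exprToDNF <- function(e) {
  clauses <- .nnfClauses(.toNNF(e))
  if (length(clauses) == 0L) return(list())
  keys <- vapply(clauses, .clauseKey, character(1))
  clauses <- clauses[!duplicated(keys)]
  # absorption: drop any clause that is a superset of another
  keep <- rep(TRUE, length(clauses))
  for (i in seq_along(clauses)) {
    for (j in seq_along(clauses)) {
      if (i == j || !keep[j]) next
      small <- clauses[[j]]
      big <- clauses[[i]]
      if (length(small) < length(big) &&
          all(names(small) %in% names(big)) &&
          all(big[names(small)] == small)) {
        keep[i] <- FALSE
        break
      }
      if (length(small) == 0L && length(big) > 0L) {
        keep[i] <- FALSE
        break
      }
    }
  }
  clauses <- clauses[keep]
  keys <- vapply(clauses, .clauseKey, character(1))
  clauses[order(keys, method = "radix")]
}

.dnfToString <- function(dnf) {
  if (length(dnf) == 0L) return("0")
  parts <- vapply(dnf, function(clause) {
    if (length(clause) == 0L) return("1")
    lits <- ifelse(clause == 1L, names(clause), paste0("!", names(clause)))
    if (length(lits) > 1L) paste0("(", paste(lits, collapse = " & "), ")") else lits
  }, character(1))
  paste(parts, collapse = " | ")
}

.evalDNF <- function(dnf, mat) {
  if (length(dnf) == 0L) return(rep.int(0L, nrow(mat)))
  v <- rep.int(0L, nrow(mat))
  for (clause in dnf) {
    if (length(clause) == 0L) return(rep.int(1L, nrow(mat)))
    cv <- rep.int(1L, nrow(mat))
    for (nm in names(clause)) {
      cv <- cv & (mat[, nm] == clause[[nm]])
    }
    v <- v | cv
  }
  as.integer(v)
}
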