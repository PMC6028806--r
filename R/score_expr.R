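## ---------------------------------------------------------------------------
## Safe scoring-expression grammar. Experiment files are untrusted input, so
## the scoring formula is evaluated by a purpose-built recursive-descent
## parser over a whitelisted grammar — never by general code evaluation.
##
##   expr    := cmp { ('<'|'>'|'<='|'>='|'=='|'!=') cmp }
##   cmp     := term { ('+'|'-') term }
##   term    := unary { ('*'|'/') unary }
##   unary   := ['-'|'+'] power
##   power   := atom [ '^' unary ]
##   atom    := number | name | name '(' expr {',' expr} ')' | '(' expr ')'
##
## Bound names: expt, sim, sem, range. Functions: sum, mean, sqrt, abs,
## min, max. Arithmetic is elementwise with the usual recycling of scalars;
## sum/mean reduce to scalars.
## ---------------------------------------------------------------------------

SCORE_FUNS <- c("sum", "mean", "sqrt", "abs", "min", "max")
SCORE_VARS <- c("expt", "sim", "sem", "range")

score_tokenize <- function(src) {
  toks <- list()
  i <- 1L; n <- nchar(src)
  push <- function(type, text) toks[[length(toks) + 1L]] <<- list(type = type, text = text)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    two <- substr(src, i, i + 1L)
    if (two %in% c("<=", ">=", "==", "!=")) { push("op", two); i <- i + 2L; next }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",", "<", ">")) {
      push(if (ch %in% c("(", ")", ",")) ch else "op", ch); i <- i + 1L; next
    }
    if (grepl("^[0-9.]$", ch)) {
      m <- regmatches(substr(src, i, n),
                      regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", substr(src, i, n)))
      push("num", m); i <- i + nchar(m); next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(src, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(src, i, n)))
      push("name", m); i <- i + nchar(m); next
    }
    stop_expsim("scoring formula: unexpected character '%s' at position %d", ch, i)
  }
  push("eof", "")
  toks
}

#' Parse a scoring formula into an evaluator
#'
#' @param formula expression string over the bound variables
#'   `expt`, `sim`, `sem`, `range`
#' @return a function `(env) -> numeric` where `env` is a named list binding
#'   the variables
#' @export
parse_score_formula <- function(formula) {
  toks <- score_tokenize(formula)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- advance()
    if (t$type != type)
      stop_expsim("scoring formula: expected '%s', found '%s'", type, t$text)
    t
  }

  parse_atom <- function() {
    t <- advance()
    if (t$type == "num") {
      v <- as.numeric(t$text)
      return(function(env) v)
    }
    if (t$type == "name") {
      nm <- t$text
      if (peek()$type == "(") {
        if (!(nm %in% SCORE_FUNS))
          stop_expsim("scoring formula: unknown function '%s' (allowed: %s)",
                      nm, paste(SCORE_FUNS, collapse = ", "))
        advance()
        args <- list(parse_expr())
        while (peek()$type == ",") { advance(); args[[length(args) + 1L]] <- parse_expr() }
        expect(")")
        f <- switch(nm, sum = function(x) sum(x), mean = function(x) mean(x),
                    sqrt = sqrt, abs = abs,
                    min = function(...) do.call(pmin_or_min, list(...)),
                    max = function(...) do.call(pmax_or_max, list(...)))
        if (nm %in% c("min", "max")) {
          return(function(env) do.call(f, lapply(args, function(a) a(env))))
        }
        if (length(args) != 1L)
          stop_expsim("scoring formula: %s() takes exactly one argument", nm)
        a1 <- args[[1L]]
        return(function(env) f(a1(env)))
      }
      if (!(nm %in% SCORE_VARS))
        stop_expsim("scoring formula: unbound name '%s' (allowed: %s)",
                    nm, paste(SCORE_VARS, collapse = ", "))
      return(function(env) {
        v <- env[[nm]]
        if (is.null(v)) stop_expsim("scoring formula references '%s' but it is not available for this experiment", nm)
        v
      })
    }
    if (t$type == "(") { e <- parse_expr(); expect(")"); return(e) }
    stop_expsim("scoring formula: unexpected token '%s'", t$text)
  }

  parse_power <- function() {
    base <- parse_atom()
    if (peek()$type == "op" && peek()$text == "^") {
      advance()
      ex <- parse_unary()
      return(function(env) base(env) ^ ex(env))
    }
    base
  }

  parse_unary <- function() {
    if (peek()$type == "op" && peek()$text %in% c("-", "+")) {
      sgn <- advance()$text
      e <- parse_power()
      if (sgn == "-") return(function(env) -e(env))
      return(e)
    }
    parse_power()
  }

  parse_term <- function() {
    e <- parse_unary()
    while (peek()$type == "op" && peek()$text %in% c("*", "/")) {
      op <- advance()$text
      rhs <- parse_unary()
      e <- local({
        lhs <- e; r <- rhs; o <- op
        if (o == "*") function(env) lhs(env) * r(env)
        else function(env) {
          den <- r(env)
          if (any(den == 0)) stop_expsim("scoring formula: division by zero")
          lhs(env) / den
        }
      })
    }
    e
  }

  parse_cmp <- function() {
    e <- parse_term()
    while (peek()$type == "op" && peek()$text %in% c("+", "-")) {
      op <- advance()$text
      rhs <- parse_term()
      e <- local({
        lhs <- e; r <- rhs; o <- op
        if (o == "+") function(env) lhs(env) + r(env)
        else function(env) lhs(env) - r(env)
      })
    }
    e
  }

  parse_expr <- function() {
    e <- parse_cmp()
    while (peek()$type == "op" && peek()$text %in% c("<", ">", "<=", ">=", "==", "!=")) {
      op <- advance()$text
      rhs <- parse_cmp()
      e <- local({
        lhs <- e; r <- rhs; o <- op
        fn <- switch(o, "<" = `<`, ">" = `>`, "<=" = `<=`, ">=" = `>=`,
                     "==" = `==`, "!=" = `!=`)
        function(env) as.numeric(fn(lhs(env), r(env)))
      })
    }
    e
  }

  body <- parse_expr()
  if (peek()$type != "eof")
    stop_expsim("scoring formula: trailing input at '%s'", peek()$text)
  body
}

pmin_or_min <- function(...) {
  args <- list(...)
  if (length(args) == 1L) min(args[[1L]]) else do.call(pmin, args)
}
pmax_or_max <- function(...) {
  args <- list(...)
  if (length(args) == 1L) max(args[[1L]]) else do.call(pmax, args)
}
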