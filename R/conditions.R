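# Structured error conditions. Every user-facing failure in the package
# signals one of these classes so callers (and the CLI) can map failures to
# exit codes without string matching.

kg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "kg_error", "error"),
                      call = call))
}

kg_validation_error <- function(msg) kg_stop(msg, "kg_validation_error")
kg_schema_error     <- function(msg) kg_stop(msg, "kg_schema_error")
kg_io_error         <- function(msg) kg_stop(msg, "kg_io_error")

kg_parse_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  kg_stop(msg, "kg_parse_error")
}

kg_generic_formula_error <- function(formula) {
  kg_stop(sprintf("generic formula: '%s'", formula),
          c("kg_generic_formula", "kg_parse_error"))
}

kg_unmapped_namespace_error <- function(token, context) {
  kg_stop(sprintf("unmapped namespace token '%s' (context: %s)",
                  token, context),
          "kg_unmapped_namespace")
}
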