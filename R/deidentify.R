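#' Pseudonym provider
#'
#' Deterministic, one-way replacement of identifying values by opaque tokens.
#' The provider is a keyed construction: a pseudonym is the HMAC-SHA-256 of
#' the value under a per-domain key derived from the provider secret,
#' truncated to 24 bytes and base64url-encoded, giving a fixed-length
#' 32-character token over a URL-safe alphabet. Within a domain the mapping is
#' deterministic (the same patient always receives the same pseudonym, so
#' linkability within a site is preserved) and collision-free with
#' overwhelming probability; across domains the same value maps to unrelated
#' tokens. Without the secret the original value cannot be recovered.
#'
#' The provider interface (a `domains` set plus `pseudonym_for()`) is the
#' integration point for external pseudonymization services; swapping in a
#' networked service requires no change to the pipeline code.
#'
#' @param secret Key material (character scalar). If `NULL`, taken from the
#'   `ONCOFED_PSEUDONYM_SECRET` environment variable.
#' @param domains Character vector of registered pseudonym namespaces.
#' @return An object of class `pseudonym_provider`.
#' @export
pseudonym_provider <- function(secret = NULL, domains = "patient") {
  secret <- secret %||% Sys.getenv("ONCOFED_PSEUDONYM_SECRET", "")
  if (!nzchar(secret)) {
    abort(paste0("no pseudonym secret: pass `secret` or set ",
                 "ONCOFED_PSEUDONYM_SECRET"))
  }
  structure(list(domains = unique(domains), secret = secret),
            class = "pseudonym_provider")
}

#' @export
print.pseudonym_provider <- function(x, ...) {
  cat("<pseudonym_provider> domains:", paste(x$domains, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pseudonym_provider
#' @param provider A `pseudonym_provider`.
#' @param domain Namespace the value belongs to (must be registered).
#' @param value Character vector of values to pseudonymize.
#' @return `pseudonym_for()`: a character vector of 32-character URL-safe
#'   tokens, one per element of `value`.
#' @examples
#' prov <- pseudonym_provider(secret = "example-secret")
#' pseudonym_for(prov, "patient", c("P0001", "P0002"))
#' @export
pseudonym_for <- function(provider, domain, value) {
  stopifnot(inherits(provider, "pseudonym_provider"))
  if (!domain %in% provider$domains) {
    abort(paste0("unregistered pseudonym domain: ", domain))
  }
  key <- paste0(provider$secret, "|", domain)
  hex <- openssl::sha256(value, key = key)
  vapply(hex, function(h) {
    raw <- as.raw(strtoi(substring(h, seq(1, 47, 2), seq(2, 48, 2)), 16L))
    tok <- openssl::base64_encode(raw)
    chartr("+/", "-_", tok)
  }, character(1), USE.NAMES = FALSE)
}

#' Deidentification rule configuration
#'
#' An ordered rule list `(resource_type, field_path, action)` with actions
#' `pseudonymize` (replace via the provider, naming a domain), `remove`
#' (strip the field) and `keep`. Field paths not named by a rule fall under
#' `default_action`. Rules are validated against the known resource fields at
#' load time, so a typo fails the run before any bundle is touched.
#'
#' @param path Path to a rules YAML, or `NULL` for the packaged default
#'   (`deident_default.yaml`: pseudonymize `Patient.identifier`, remove
#'   `Patient.quasi_identifier`, keep the analysis fields).
#' @return A list of class `deident_config` with a `rules` tibble and
#'   `default_action`.
#' @export
read_deident_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "deident_default.yaml",
                                package = "oncofed", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(raw$rules, function(r) {
    tibble(resource_type = r$resource_type, field_path = r$field_path,
           action = r$action, domain = r$domain %||% NA_character_)
  })
  known <- list(
    Patient = c("identifier", "gender", "quasi_identifier"),
    Condition = c("code", "onsetDateTime", "subject")
  )
  for (i in seq_len(nrow(rules))) {
    rt <- rules$resource_type[i]
    if (!rt %in% names(known)) {
      abort(paste0("deidentification rule names unknown resource type: ", rt))
    }
    if (!rules$field_path[i] %in% known[[rt]]) {
      abort(paste0("deidentification rule names unknown field path: ",
                   rt, ".", rules$field_path[i]))
    }
    if (rules$action[i] == "pseudonymize" && is.na(rules$domain[i])) {
      abort("pseudonymize rule must name a domain")
    }
  }
  if (anyDuplicated(paste(rules$resource_type, rules$field_path))) {
    abort("duplicate field_path for a resource_type in deidentification rules")
  }
  structure(list(rules = rules, default_action = raw$default_action %||% "remove"),
            class = "deident_config")
}

rule_action <- function(config, resource_type, field) {
  i <- which(config$rules$resource_type == resource_type &
               config$rules$field_path == field)
  if (length(i)) {
    list(action = config$rules$action[i[1]], domain = config$rules$domain[i[1]])
  } else {
    list(action = config$default_action, domain = NA_character_)
  }
}

#' Deidentify FHIR bundles
#'
#' Applies the configured rules to each bundle: the patient identifier value
#' is replaced by its pseudonym, `remove`-ruled fields are stripped, analysis
#' fields are kept, and the `Condition.subject` reference is left pointing at
#' the bundle's Patient resource id (which is derived from report provenance,
#' not from the patient identifier, so bundles stay reference-closed without
#' leaking the identifier). The output bundle carries `deidentified = TRUE`;
#' the flattening stage refuses bundles without that flag.
#'
#' @param bundles A list of `fhir_bundle` objects (or a single bundle for
#'   `deidentify_bundle()`).
#' @param config A [read_deident_config()] rule set.
#' @param provider A [pseudonym_provider()].
#' @return Deidentified bundle(s) of the same shape.
#' @export
deidentify_bundles <- function(bundles, config, provider) {
  stopifnot(inherits(config, "deident_config"),
            inherits(provider, "pseudonym_provider"))
  # one vectorized provider call over all identifier values
  values <- vapply(bundles, function(b) {
    bundle_patient(b)$identifier[[1]]$value
  }, character(1))
  pat_rule <- rule_action(config, "Patient", "identifier")
  pseudonyms <- switch(pat_rule$action,
    pseudonymize = pseudonym_for(provider, pat_rule$domain, values),
    keep = values,
    remove = rep(NA_character_, length(values))
  )
  purrr::map2(bundles, pseudonyms, function(b, pn) {
    deidentify_one(b, config, pn)
  })
}

#' @rdname deidentify_bundles
#' @param bundle A single `fhir_bundle`.
#' @export
deidentify_bundle <- function(bundle, config, provider) {
  deidentify_bundles(list(bundle), config, provider)[[1]]
}

deidentify_one <- function(bundle, config, pseudonym) {
  patient <- bundle_patient(bundle)
  condition <- bundle_condition(bundle)
  if (is.na(pseudonym)) {
    patient$identifier <- NULL
  } else {
    patient$identifier[[1]]$value <- pseudonym
  }
  for (f in c("gender", "quasi_identifier")) {
    if (!is.null(patient[[f]]) &&
        rule_action(config, "Patient", f)$action == "remove") {
      patient[[f]] <- NULL
    }
  }
  for (f in c("code", "onsetDateTime", "subject")) {
    if (!is.null(condition[[f]]) &&
        rule_action(config, "Condition", f)$action == "remove") {
      condition[[f]] <- NULL
    }
  }
  bundle$entry <- list(list(resource = patient), list(resource = condition))
  bundle$deidentified <- TRUE
  bundle
}
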