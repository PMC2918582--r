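---
title: "The s3db core model: two-tier predication and operator-state percolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The s3db core model: two-tier predication and operator-state percolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s3db)
```

## The model

An s3db store types every data element as one of seven entity kinds —
deployment, project, collection, rule, item, statement, user — and
restricts the triples that may be asserted between them to twelve
relationship kinds, each with a fixed domain and range
(`s3db_relation_kinds()`).  The kinds carry a canonical order by their
initials, `[D, P, C, R, I, S, U]`, which fixes the layout of the
transition matrix below.

The heart of the schema is a two-tier predication pattern.  A *rule*
describes a piece of domain: it binds a subject collection, a
predicate item and an object that is either another collection or an
opaque resource (a foreign URI such as `foaf:firstName`, or a bare
literal name).  A *statement* instantiates a rule with an observation,
using the rule itself as predicate; its subject must be an item of the
rule's subject collection, and its object is an item of the rule's
object collection — or, for opaque-object rules, a literal value
stored as text.  Because description and instantiation are distinct
triples, the domain can be edited without corrupting data:
`update_rule_object()` re-points an opaque rule object while every
dependent statement keeps its URI and literal value (this invariant is
asserted by a before/after diff in the test suite).  The pattern is
enforced purely by assertion-time validation and `validate_store()`;
there is deliberately no description-logic reasoning.

Assumptions baked into the schema layer:

* **One deployment per store.**  Distribution across deployments is a
  deployment concern, not a model concern here; foreign URIs are
  handled as external resources.
* **No cardinality limits.**  An item may belong to many collections;
  a collection may subject many rules (`validate_store()` never
  counts, only types).
* **Literals are opaque text.**  No datatype system; a literal object
  is whatever string was asserted.
* **Predicate items without a collection are legal but flagged** as
  `W_PREDICATE_NO_COLLECTION` warnings — the worked example itself
  defers choosing a collection for its predicate items, so rejecting
  them would be wrong, but silently accepting them forever would hide
  modelling debt.

## Operator states

An operator is a discrete variable with `n ≥ 1` ordered states over a
user/entity pair; each state has a recessive (lower-case) and a
dominant (upper-case) written form, and the operator responds only to
a state's index — case matters only to resolution.  Operators that
share one alphabet can be bundled (`operator_bundle()`); with `m`
operators a state string is read as a sequence of m-tuples, position
`j` of each tuple belonging to operator `j`.

Three functions define propagation:

**Merge.**  `merge_states()` resolves a set of assigned states to one:
the dominant state of minimum index if any dominant state is present,
otherwise the recessive state of maximum index, case preserved.  The
published rendering of this resolution is not directly executable; the
rule implemented here is pinned because it reproduces both canonical
resolutions (`merge({b,c,d}) = d` at index 3,
`merge({b,c,C,D}) = C` at index 2) and the observation that under the
resolution the merged index 2 outranks 3 when dominance enters.  The
test suite additionally checks merge against an independently coded
brute-force restatement over every two-symbol subset of a three-state
alphabet, and checks commutativity, associativity and idempotence on
random symbol sets.

**Migrate.**  `migrate_state(s, m)` first normalizes `s` to a whole
number of m-tuples by borrowing from the position immediately to the
left — i.e. right-padding with the last symbol.  This padding rule is
pinned because it is the unique single rule that reproduces all four
canonical `m = 3` examples (`'a' → 'aaa'`, `'abc' → 'abc'`,
`'abcb' → 'bbb'`, `'abcbc' → 'bcc'`).  A normalized string of exactly
one tuple passes unchanged; a plural string leaves its first tuple
behind as the source's effective state and passes the remainder
(`'abCd', m = 1 → 'bCd'`).  Normalization is applied once, at
assignment parse time (`parse_state_string()`), and is idempotent
inside `migrate_state()` so both entry points agree.

**Percolate.**  `percolate()` seeds a pool of strings at each directly
assigned entity, then migrates every pooled string along every edge of
the instance graph until the pools are closed under one more step.
The instance graph projects the store's relation instances through a
Boolean transition matrix over kind initials: the default
(`s3db_transition_matrix()`) has exactly the ten true cells derivable
from the twelve relationship kinds (C→R and I→S each licensed twice).
Any other Boolean matrix may be substituted — the propagation
machinery is independent of this particular core model.

Two design choices deserve justification:

* **Pools keep whole strings; merging happens at reporting time.**
  An alternative reading merges each entity's states at the end of
  every iteration.  Collapsing pools to single symbols during
  iteration would destroy the depth-indexed expressivity of plural
  states (the first tuple of `'abCd'` is the local effective state,
  the remainder belongs to descendants), so this package keeps the
  full string sets and applies merge only in `effective_state()`.
  For singular states the two readings coincide at the fixed point,
  which is all the fixed-point condition constrains.
* **Termination and confluence.**  Every pooled string is a
  tuple-suffix of one of finitely many assignments, so pools can only
  grow within a finite set, and strings of one tuple migrate to
  themselves — cycles (only `UU` can create them) terminate.  Because
  the update is a union, the fixed point is independent of edge
  processing order; the suite verifies this by re-percolating under
  reversed and randomly permuted relation orders, and verifies the
  pools themselves against an independently coded oracle that
  enumerates walks by Boolean adjacency-matrix powers (a string of
  `t` tuples contributes its `k`-times-migrated form to entities
  reached by walks of exact length `k < t − 1`, and its terminal
  tuple to everything reachable at depth `≥ t − 1`).

## Permissions

The shipped configuration (`s3db_default_bundle()`, also in
`inst/extdata/view-edit-use.yaml`) defines `view`, `edit`, `use` over
the ordered states `all > self > none`, symbols `a/b/c`, index 1 most
permissive.  `is_allowed()` maps the effective state to a decision:
index 1 allows, the last index denies, intermediate indexes are read
as *self* — allowed only when the entity's recorded `creator` is the
requesting user.  Two published namings of the state labels coexist
(`none/self/all` vs `yes/self/no`); the package treats labels as
display names over canonical indexes, so either set can be configured.
Entities reached by no state use the bundle's `default_decision`,
deny unless configured otherwise — a default the model itself leaves
open, chosen here as the safe one for mixed public/private data.

Dominance is what makes local exceptions cheap: a recessive `a`
assigned at a collection grants `all` to every item, and a single
dominant `C` at one item overrides it there — and only there, since
items receive states only from collections.  The suite asserts this
sibling-isolation property on every generated store that has a
collection with at least two members.

**Between-user propagation.**  `UU` links let assignments migrate from
user to user (one migration step per hop), enabling group- and
role-like constructs.  The reference behaviour keeps this off, so
`percolate(..., enable_uu = TRUE)` is an explicit opt-in; when off,
entity-level user→user edges are excluded from the instance graph so
the two mechanisms cannot double-apply.  Percolation is always
computed per user: operators predicate a single user subject.

## Serialization

Stores interchange through a deliberately narrow Turtle dialect: one
triple per line, `@prefix` declarations, plain or datatyped quoted
literals.  The *reified* style is normative — every entity typed, every
relation explicit, statement literals as `s3db:literalObject`,
assignments packed into a datatyped `s3db:operator` literal
(`"target|bundle|state"^^s3db:assignment`) — because compact statement
triples alone cannot round-trip statement URIs.  The *compact* style
adds the derived one-triple-per-statement view
(`:I_Mary :R_people_in_places :I_Houston .`).  `import_turtle()`
validates typing on ingest (violations abort, naming offenders),
registers foreign-namespace subjects as external resources, skips
unknown predicates with a warning (error under `strict = TRUE`), and
recomputes mint counters so sequential URI generation continues above
imported names.  The s3db namespace URI itself is a placeholder
declared in one place, since the vocabulary's published snippets leave
it open.  No general-purpose Turtle parser is attempted or claimed.

One normalization worth noting: the worked example's prose names the
collection of places both `C_places` and `C_place`; the fixture uses
`C_places` throughout, and writes the statement object as the item URI
`:I_Houston`.

## The synthetic generator

`generate_random_store()` emulates the shape of a populated store:
projects under the deployment, collections under random projects,
items joining one or more collections (`membership_density` extra
memberships), rules over random subject collections and predicate
items with a `literal_fraction` of opaque objects, statements drawn
only from rules whose collections are populated, optional `UU` links,
and random well-formed assignments of up to `max_tuple_depth`
m-tuples with a configurable fraction of dominant symbols.  Every
store it emits is valid by construction and fully determined by its
seed (RNG state is isolated with `withr`).

What it does *not* emulate: real label vocabularies, skewed degree
distributions, contradictory multi-investigator schemas, or stores
large enough to stress memory.  Passing the property campaigns
therefore demonstrates correctness of the algebra and of
serialization on well-formed stores of realistic shape, not
performance at repository scale.  The campaigns run one hundred seeds
at ≤ 50 entities per store (2 projects, 3 collections, 8 items, 3
rules, 6 statements, 2 users, 3 assignments, tuple depth ≤ 3) —
sizes at which the walk-enumeration oracle is exact and the whole
suite completes in about two minutes.

## Degenerate inputs and edge cases

* Empty state strings, `m < 1`, symbols outside the alphabet: typed
  errors (`E_PARSE`, `E_USAGE`) with position information.
* Merge of an empty set is undefined (`E_MERGE_UNDEFINED`); callers
  map it to "unassigned".
* A second deployment: `E_DUP_ROOT`.  Deletion with dependents:
  refused (`E_DEPENDENTS`) unless `cascade = TRUE`, which removes
  dependents transitively (a deleted collection takes its rules, the
  rules their statements) — cascade semantics are this package's
  choice, made conservative because the model leaves them open.
* Re-asserting an existing relation is a no-op (set semantics).
* URI minting is sequential per kind under the deployment base for
  reproducibility, with an opt-in random mode; minting is a pure
  function of store contents, so replaying a construction sequence
  replays its URIs.
* The published relationship list prints one relationship twice and
  omits the two user relationships in its informal enumeration; the
  numbered rows 1–12 are taken as authoritative, giving `DU` and `UU`
  full standing.

## Limitations

No query language, REST protocol, SPARQL mapping, or network
transport; no RDF/XML or JSON-LD; no authentication.  The transition
matrix is used as an edge mask rather than through explicit
matrix-vector products — extensionally equivalent and cheaper.  The
permission model intentionally stops at allow/deny per operator;
richer operator applications (retrieval priority, workflow triggers)
fit the same algebra but are not shipped.
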