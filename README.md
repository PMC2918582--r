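# s3db

Two-tier RDF data management with propagated user-operator states, in R.

## The problem

Biomedical data acquisition is fluid: the description of a domain
(which attributes exist, what they relate) is redesigned continually,
while the observations already collected must survive every redesign.
At the same time, mixing public and private data demands access
control that is finer than per-database but cheaper than per-record.

The S3DB core model addresses both with two abstractions:

1.  **A typed RDF design pattern** that separates *domain* from its
    *observational instantiation*.  Every data element is one of seven
    entity kinds — deployment (the root), project, collection, item,
    rule, statement, user — connected by twelve validated
    relationships.  A **rule** is a dyadic predicate
    `(collection, predicate item, collection-or-resource)` describing
    the domain ("people live in places"); a **statement** instantiates
    a rule with an observation (`Mary → Houston`), *using the rule
    itself as its predicate*.  Because the two tiers are distinct
    triples, the domain can be edited freely — e.g. renaming the
    attribute a rule points at — without touching a single statement.

2.  **A finite-state machinery for user operators.**  An operator `f`
    (e.g. a `view` permission) has `n` ordered states, each with a
    recessive (lower-case) and dominant (upper-case) written form.
    Three functions resolve who-may-do-what everywhere in the store:

    -   **merge(S)** — of all states assigned to a user/entity pair,
        directly or inherited, the *lowest-index dominant* state wins
        if any dominant state is present; otherwise the
        *highest-index recessive* one.  With states indexed
        `{b, c, d}`: `merge({b,c,d}) = d` (index 3),
        `merge({b,c,C,D}) = C` (index 2).
    -   **migrate(s, m)** — states pass from domain to instantiation
        along the edges licensed by a Boolean 7×7 transition matrix
        over `[D, P, C, R, I, S, U]`.  With `m` operators migrating
        simultaneously a string is read as m-tuples: a singular state
        passes as is (`migrate('a', 3) = 'aaa'`,
        `migrate('abc', 3) = 'abc'`), a plural one leaves its first
        tuple behind as the local effective state and passes the rest
        (`migrate('abcb', 3) = 'bbb'`, `migrate('abCd', 1) = 'bCd'`),
        and missing positions borrow from the left
        (`migrate('abcbc', 3) = 'bcc'`).
    -   **percolate** — iterated migration plus merging until the
        effective state of every entity no longer changes (a finite
        fixed point, independent of edge order).

The default configuration is the View/Edit/Use permission bundle:
three operators sharing the ordered states `all > self > none`
(symbols `a`, `b`, `c`), with `self` meaning "only on entities the
requesting user created" and unassigned entities denied.

## Worked example

```r
library(s3db)

store <- build_mary_fixture(s3db_store("http://example.org/demo")) |>
  add_user(label = "ann") |>
  assign_state("ann", "C_person", "abc")   # one tuple: view=all, edit=self, use=none
store
#> <s3db_store> http://example.org/demo
#>   entities: deployment=1 project=1 collection=2 rule=2 item=4 statement=2 user=1
#>   external resources: 1
#>   relations: 19  assignments: 1

pool <- percolate(store, "ann")
pool
#> <s3db_pool> user http://example.org/demo/U1
#>   entities with states: 6  strings: 6  sweeps: 2

effective_states(pool)
#> # A tibble: 18 × 6
#>    entity                           operator symbol index state dominant
#>  1 …/C_person                       view     a          1 all   FALSE
#>  2 …/C_person                       edit     b          2 self  FALSE
#>  3 …/C_person                       use      c          3 none  FALSE
#>  4 …/I_Mary                         view     a          1 all   FALSE
#>  ⋮  (same three states at every downstream rule and statement)

is_allowed(store, pool, "ann", "I_Mary", "view")
#> [1] TRUE
```

The single three-letter assignment on the collection of people
percolated to its items, to both rules it subjects, and to their
statements: `view` resolves to `all` (index 1, allow), `edit` to
`self`, `use` to `none` everywhere downstream.  `tidy(pool)` and
`glance(pool)` give per-string and summary views; `autoplot(store)`
draws the instance graph and `autoplot(pool)` the effective-state
map.

Stores round-trip through a Turtle/N3 dialect
(`export_turtle()` / `import_turtle()`; the compact style writes each
statement the way the two-tier pattern reads,
`:I_Mary :R_people_in_places :I_Houston .`), and
`generate_random_store(seed = …)` builds arbitrary valid stores for
testing.  A command-line wrapper
(`system.file("cli", "s3db", package = "s3db")`) exposes `init`,
`add`, `link`, `assign`, `percolate`, `effective`, `allowed`,
`validate`, `export`, `import` and `fixture` subcommands over a
Turtle-file store (exit codes: 0 ok, 1 validation failure, 2 usage).

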