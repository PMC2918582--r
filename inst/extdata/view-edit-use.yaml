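## Default permission operator bundle: three operators sharing one
## ordered three-state alphabet.  Index 1 is the most permissive state;
## symbols are written lower-case (recessive) and upper-cased for the
## dominant form in assignment strings.
operators:
  - name: view
    states: [all, self, none]
    symbols: [a, b, c]
  - name: edit
    states: [all, self, none]
    symbols: [a, b, c]
  - name: use
    states: [all, self, none]
    symbols: [a, b, c]
default_decision: deny
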