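# Warhead taxonomy rule file (editable).
#
# Each rule: a warhead class, its reaction class/type, the anchor residue it
# reacts with, a priority (higher = more specific, matched first) and one or
# more core patterns. Patterns are explicit heavy-atom graphs:
#   atoms:  element symbols; "*" = any heavy atom, "X" = halogen (F/Cl/Br/I)
#   bonds:  [i, j, order] with 1-based atom indices; order 0 matches any
#   link_atom: 1-based index of the pattern atom that forms the covalent bond
#   max_deg: optional per-atom cap on heavy-atom degree (0 = unconstrained),
#            used to pin aldehyde/ketone carbons against amide/ester carbons
#   smarts: annotation only (the matcher consumes the explicit graph)
version: 1
rules:
  - warhead_class: "Lactam"
    reaction_class: "Ring Opening"
    reaction_type: "Ring Opening by Ser"
    anchor: SER
    priority: 200
    patterns:
      - smarts: "O=C1CCN1"
        atoms: ["C", "O", "N", "C", "C"]
        bonds: [[1, 2, 2], [1, 3, 1], [3, 4, 1], [4, 5, 1], [5, 1, 1]]
        link_atom: 1
      - smarts: "O=C1CCCN1"
        atoms: ["C", "O", "N", "C", "C", "C"]
        bonds: [[1, 2, 2], [1, 3, 1], [3, 4, 1], [4, 5, 1], [5, 6, 1], [6, 1, 1]]
        link_atom: 1
  - warhead_class: "Lactone"
    reaction_class: "Ring Opening"
    reaction_type: "Ring Opening by Ser"
    anchor: SER
    priority: 195
    patterns:
      - smarts: "O=C1CCO1"
        atoms: ["C", "O", "O", "C", "C"]
        bonds: [[1, 2, 2], [1, 3, 1], [3, 4, 1], [4, 5, 1], [5, 1, 1]]
        link_atom: 1
      - smarts: "O=C1CCCO1"
        atoms: ["C", "O", "O", "C", "C", "C"]
        bonds: [[1, 2, 2], [1, 3, 1], [3, 4, 1], [4, 5, 1], [5, 6, 1], [6, 1, 1]]
        link_atom: 1
      - smarts: "O=C1CCCCO1"
        atoms: ["C", "O", "O", "C", "C", "C", "C"]
        bonds: [[1, 2, 2], [1, 3, 1], [3, 4, 1], [4, 5, 1], [5, 6, 1], [6, 7, 1], [7, 1, 1]]
        link_atom: 1
  - warhead_class: "Heterocyclic"
    reaction_class: "Ring Opening"
    reaction_type: "Ring Opening by Cys"
    anchor: CYS
    priority: 190
    patterns:
      - smarts: "C1CO1"
        atoms: ["C", "C", "O"]
        bonds: [[1, 2, 1], [2, 3, 1], [3, 1, 1]]
        link_atom: 1
      - smarts: "C1CN1"
        atoms: ["C", "C", "N"]
        bonds: [[1, 2, 1], [2, 3, 1], [3, 1, 1]]
        link_atom: 1
  - warhead_class: "Boronic acid"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Ser"
    anchor: SER
    priority: 185
    patterns:
      - smarts: "B(O)O"
        atoms: ["B", "O", "O"]
        bonds: [[1, 2, 1], [1, 3, 1]]
        link_atom: 1
  - warhead_class: "Phosphonyl"
    reaction_class: "Nucleophilic Substitution"
    reaction_type: "Nucleophilic Substitution by Ser"
    anchor: SER
    priority: 180
    patterns:
      - smarts: "P=O"
        atoms: ["P", "O"]
        bonds: [[1, 2, 2]]
        link_atom: 1
  - warhead_class: "Nitrile(cys)"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Cys"
    anchor: CYS
    priority: 175
    patterns:
      - smarts: "C#N"
        atoms: ["C", "N"]
        bonds: [[1, 2, 3]]
        link_atom: 1
  - warhead_class: "Nitrile(ser)"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Ser"
    anchor: SER
    priority: 174
    patterns:
      - smarts: "C#N"
        atoms: ["C", "N"]
        bonds: [[1, 2, 3]]
        link_atom: 1
  - warhead_class: "Alkyne"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Cys"
    anchor: CYS
    priority: 170
    patterns:
      - smarts: "C#C"
        atoms: ["C", "C"]
        bonds: [[1, 2, 3]]
        link_atom: 1
  - warhead_class: "Guanyl"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Cys"
    anchor: CYS
    priority: 165
    patterns:
      - smarts: "N=C(N)N"
        atoms: ["N", "C", "N", "N"]
        bonds: [[1, 2, 2], [2, 3, 1], [2, 4, 1]]
        link_atom: 2
  - warhead_class: "Halide"
    reaction_class: "Nucleophilic Substitution"
    reaction_type: "Nucleophilic Substitution (cys)"
    anchor: CYS
    priority: 160
    patterns:
      - smarts: "O=CC[F,Cl,Br,I]"
        atoms: ["O", "C", "C", "X"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 1]]
        link_atom: 3
      - smarts: "C[F,Cl,Br,I]"
        atoms: ["C", "X"]
        bonds: [[1, 2, 1]]
        link_atom: 1
  - warhead_class: "Alkene(cys)"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Cys"
    anchor: CYS
    priority: 150
    patterns:
      - smarts: "C=CC=O"
        atoms: ["C", "C", "C", "O"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 2]]
        link_atom: 1
      - smarts: "C=CC#N"
        atoms: ["C", "C", "C", "N"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 3]]
        link_atom: 1
      - smarts: "C=CS(=O)=O"
        atoms: ["C", "C", "S", "O", "O"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 2], [3, 5, 2]]
        link_atom: 1
  - warhead_class: "Carbonyl(cys)"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Cys"
    anchor: CYS
    priority: 140
    patterns:
      - smarts: "[CX2H1]=O"
        atoms: ["C", "O"]
        bonds: [[1, 2, 2]]
        link_atom: 1
        max_deg: [2, 1]
      - smarts: "CC(=O)C"
        atoms: ["C", "C", "O", "C"]
        bonds: [[1, 2, 1], [2, 3, 2], [2, 4, 1]]
        link_atom: 2
        max_deg: [0, 3, 1, 0]
  - warhead_class: "Carbonyl(ser)"
    reaction_class: "Nucleophilic Addition"
    reaction_type: "Nucleophilic Addition by Ser"
    anchor: SER
    priority: 139
    patterns:
      - smarts: "O=CC(=O)N"
        atoms: ["O", "C", "C", "O", "N"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 2], [3, 5, 1]]
        link_atom: 2
      - smarts: "[CX2H1]=O"
        atoms: ["C", "O"]
        bonds: [[1, 2, 2]]
        link_atom: 1
        max_deg: [2, 1]
      - smarts: "CC(=O)C"
        atoms: ["C", "C", "O", "C"]
        bonds: [[1, 2, 1], [2, 3, 2], [2, 4, 1]]
        link_atom: 2
        max_deg: [0, 3, 1, 0]
  - warhead_class: "Sulfydryl"
    reaction_class: "Disulfide Formation"
    reaction_type: "Disulfide Formation"
    anchor: CYS
    priority: 120
    patterns:
      - smarts: "SS"
        atoms: ["S", "S"]
        bonds: [[1, 2, 1]]
        link_atom: 1
      - smarts: "C[SH]"
        atoms: ["C", "S"]
        bonds: [[1, 2, 1]]
        link_atom: 2
        max_deg: [0, 1]
  - warhead_class: "Others"
    reaction_class: "Nucleophilic Substitution"
    reaction_type: "Nucleophilic Substitution (cys)"
    anchor: CYS
    priority: 100
    patterns:
      - smarts: "S(=O)(=O)[F,Cl,Br,I]"
        atoms: ["S", "O", "O", "X"]
        bonds: [[1, 2, 2], [1, 3, 2], [1, 4, 1]]
        link_atom: 1
      - smarts: "O=CSC"
        atoms: ["O", "C", "S", "C"]
        bonds: [[1, 2, 2], [2, 3, 1], [3, 4, 1]]
        link_atom: 2
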