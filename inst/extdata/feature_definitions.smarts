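# Pharmacophoric feature definitions used for FCFP-style atom typing and
# assign_feature_types(). One pattern per line: <class> <SMARTS>.
# Classes: donor acceptor aromatic halogen basic acidic.
# These defaults follow the common toolkit feature invariants; edit freely.

donor [$([N;!H0;v3]),$([N;!H0;+1;v4]),$([O,S;H1;+0]),$([n;H1;+0])]

acceptor [$([O,S;H1;v2;!$(*-*=[O,N,P,S])]),$([O,S;H0;v2]),$([O,S;-]),$([N;v3;!$(N-*=[O,N,P,S])]),$([nH0;+0]),$([o,s;+0;!$([o,s]:n)])]

aromatic [a]

halogen [F,Cl,Br,I]

# protonatable nitrogens: amines whose neighbors are not carbonyl-like
basic [#7;+;!$([N+]-[O-])]
basic [N;H2;+0;$(N-[C;!$(C=[O,N,S])]);!$(N-a)]
basic [N;H2;+0;$(N-a)]
basic [N;H1;+0;$(N(-[C,c;!$([C,c]=[O,N,S])])-[C,c;!$([C,c]=[O,N,S])])]
basic [N;H0;+0;$(N(-[C,c;!$([C,c]=[O,N,S])])(-[C,c;!$([C,c]=[O,N,S])])-[C,c;!$([C,c]=[O,N,S])])]

acidic [O;H1,-1;$(O-[C,S,P]=[O,S])]
acidic [C;$(C(=O)[O;H1,-1])]
acidic [S;$(S(=O)(=O)[O;H1,-1])]
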