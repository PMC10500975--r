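==== Secondary Structure Definition by the program DSSP ====
REFERENCE  synthetic example (not a real protein)
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC
    1    1 A M   
    2    2 A K   
    3    3 A V  H
    4    4 A L  H
    5    5 A A  H
    6    6 A A  H
    7    7 A G  H
    8    8 A D  H
    9    9 A T  H
   10   10 A L  H
   11   11 A E   
   12   12 A Q   
   13   13 A W   
   14        !
   15   15 B G   
   16   16 B K   
   17   17 B E  E
   18   18 B V  E
   19   19 B T  E
   20   20 B F  E
   21   21 B V  E
   22   22 B A   
   23   23 B G   
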