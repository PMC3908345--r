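LOCUS       TESTCHR01               5000 bp    DNA     circular BCT 01-JAN-2020
DEFINITION  Synthetica prima strain T1 chromosome, complete genome.
ACCESSION   TESTCHR01
VERSION     TESTCHR01.1
SOURCE      Synthetica prima
  ORGANISM  Synthetica prima
            Bacteria; Synthetica.
FEATURES             Location/Qualifiers
     source          1..5000
                     /organism="Synthetica prima"
                     /mol_type="genomic DNA"
     CDS             900..1445
                     /locus_tag="T1_0003"
                     /product="gamma subunit"
                     /protein_id="TP_0003.1"
                     /translation="MSLNDIKQRIAGVKNTQKITSAMEMVAASKMRKAQDRMAASRPY
                     AETMRKVIGHLAHGNLEYKHPYLEERDVKRVGYLVVSTDRGLCGGLNINLFKKLLAEM"
     CDS             complement(100..705)
                     /locus_tag="T1_0001"
                     /product="alpha subunit"
                     /protein_id="TP_0001.1"
                     /translation="MQLNSTEISELIKQRIAQFNVVSEAHNEGTIVSVSDGVIRIHGL
                     ADCMQGEMISLPGNRYAIALNLERDSVGAVVMGPYADLAEGMKVKCTGRILEVPVGRG"
     CDS             400..840
                     /locus_tag="T1_0002"
                     /product="beta subunit"
                     /protein_id="TP_0002.1"
                     /translation="MKTVVIGAGVIGLSTALCIHERYHSVLQPLDIKVYADRFTPLTT
                     TDVAAGLWQPYLSDPSNPQEANWNQQTFDYLLSHVHSPNAENLGLFLISGYNLFHEAI"
     CDS             2000..2300
                     /locus_tag="T1_0004"
                     /product="degenerate transposase"
                     /pseudo
ORIGIN
//
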