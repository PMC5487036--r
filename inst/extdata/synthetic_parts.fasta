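;; Fusion-part library. his6/ha/gs_linker/gse_linker are the exact
;; public part sequences. mbp and mcherry are SYNTHETIC STAND-IN
;; sequences: random compositions constrained to the documented length
;; and average molecular mass of mature E. coli MBP (malE, 370 aa,
;; ~40.71 kDa) and mCherry (236 aa, ~26.72 kDa). Replace with the real
;; construct sequences for exact-mass work.
>pqe9_his6_leader
MRGSHHHHHHGS
>his6
HHHHHH
>ha
YPYDVPDYA
>gs_linker
GSGSGSG
>gse_linker
GSGESG
>mbp_standin
QGPQPGKVGPYPACDPVHLPPGGLCSTLIYNFQQGSFSYFNKYVYVSEVTMRYLVHIGAP
NFGGYNAYRLGYLVYIEKTRLTKKPVMKHHTQSESELALEERDAEPFFMSIGLGAKQTKE
YRRTAAEAPGAVFDCWFMNSNSLLWQMIATMLIILNFLYFLTDDEMGKKEQDTSAERSGE
GAVTGARDILSTLVPTDTPSGMLYDEPNASMDEIIPAKQRDKSPGSFSSIDGDFALVGLK
VTLEMFIPYMSHNAVRLLIVIYDAGGLQSDWMVIGGGGTKIFIGNFITKPPHIHVEKDRR
IVSAEASQVSGPYMKGCVPLTGLGDYTNFADDNDRIFAEDIHAAPLGSGAANLIPDDLPQ
CQSLVILAYE
>mcherry_standin
ISGPGNMSEDFYLRAGVCTMGEPLLLIEIETNNVFDEAAKAQGPQIRRCCHGTFGVDRHY
KAAAYYVDEMSLRRNPPLMGTSLDLFLLRREKIAVGSSGELGIGQALEANMRLLTALAWC
GYETEALASLARTRLIIILGDGEKNFVGGLDLLGRLYNYFHRATLGEKKVHFKLTGHIIP
YARHFNDDRTEAFMWDFRWAAVVPNLVVLIPPAYHILAQQTRYRTSERNEWNKDKE
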