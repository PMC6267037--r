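>seed01
DEKNQRSADEKNQRSADVERNRRMKLNDSLHDGSLPKTAQVLSEAARYIKFLQDQVEKLR
>seed02
EKNQRSADEKNQRSADEVERNRRMKLNDSLHDGSLPKTAQVLSEAARYIKFLQDQVEKLR
>seed03
KNQRSADEKNQRSADEKVERNRRMKLNDSLHDGSLPKTAQVLSEAARYIKFLQDQVEKLR
>seed04
NQRSADEKNQRSADEKNVERNRRMGLNDSLHDGSLPKTAQVLSEAARYIGFLQDQVEKLR
>seed05
QRSADEKNQRSADEKNQVEGNRRMGLNDSLHDGSLPKTAGVLSEAARYIGFLQDGVEKLR
>seed06
RSADEKNQRSADEKNQRVEGNRRMPLNDSLHDGSLPKTAGVLSEAARYIPFLQDGVEKLR
>seed07
SADEKNQRSADEKNQRSVEPNRRMPLNDSLHDGSLPKTAPVLSEAARYIPFLQDPVEKLR
>seed08
ADEKNQRSADEKNQRSAVEPNRRMWLNDSLHDGSLPKTAPVLSEAARYIWFLQDPVEKLR
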