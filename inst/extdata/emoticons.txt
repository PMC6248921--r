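:)
:-)
:))
:(
:-(
:((
;)
;-)
:D
:-D
;D
:P
:-P
:p
:-p
:O
:-O
:o
:/
:-/
:\
:|
:-|
:*
:-*
:'(
:'-(
:')
=)
=(
=D
=P
=/
<3
</3
^_^
^-^
^^
-_-
o_O
O_o
o_o
O_O
x_x
X_X
xD
XD
:3
>:(
>:)
D:
:s
:S
:$
8)
8-)
B)
B-)
\o/
T_T
;_;
._.
:-]
:]
:-[
:[
=]
=[
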