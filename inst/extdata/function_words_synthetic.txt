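# Synthetic function-word list (closed-class words) for emovoc.
a
about
above
across
after
again
against
all
along
already
also
although
always
am
among
an
and
another
any
anybody
anyone
anything
are
aren't
around
as
at
be
because
been
before
behind
being
below
between
beyond
both
but
by
can
can't
could
couldn't
did
didn't
do
does
doesn't
doing
don't
down
during
each
either
else
ever
every
everybody
everyone
everything
for
from
further
had
hadn't
has
hasn't
have
haven't
having
he
her
here
hers
herself
him
himself
his
how
i
i'd
i'll
i'm
i've
if
in
into
is
isn't
it
it's
its
itself
just
let's
may
me
might
mine
must
my
myself
near
need
neither
never
no
nobody
none
nor
not
nothing
now
of
off
often
on
once
only
onto
or
other
ought
our
ours
ourselves
out
over
own
same
shall
she
should
shouldn't
since
so
some
somebody
someone
something
sometimes
soon
still
such
than
that
that's
the
their
theirs
them
themselves
then
there
there's
these
they
they're
this
those
though
through
to
too
under
unless
until
up
upon
us
very
was
wasn't
we
we're
we've
were
weren't
what
whatever
when
where
whether
which
while
who
whoever
whom
whose
why
will
with
within
without
won't
would
wouldn't
yet
you
you're
you've
your
yours
yourself
yourselves
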